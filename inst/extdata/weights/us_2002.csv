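sex,age_group,share
Male,18-34,16.2
Male,35-54,19.4
Male,55-74,10.1
Male,75+,2.9
Female,18-34,15.7
Female,35-54,19.9
Female,55-74,11.0
Female,75+,4.8
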