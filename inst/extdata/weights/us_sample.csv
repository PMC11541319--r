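sex,age_group,share
Male,18-34,16.1
Male,35-54,16.5
Male,55-74,7.5
Male,75+,2.0
Female,18-34,22.3
Female,35-54,22.2
Female,55-74,10.0
Female,75+,3.3
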