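sex,age_group,share
Male,18-34,14.9
Male,35-54,16.3
Male,55-74,13.9
Male,75+,3.9
Female,18-34,14.5
Female,35-54,16.2
Female,55-74,15.1
Female,75+,5.2
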