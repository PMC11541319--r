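sex,age_group,share
Male,18-34,13.9
Male,35-54,13.9
Male,55-74,12.5
Male,75+,3.1
Female,18-34,18.1
Female,35-54,16.9
Female,55-74,16.0
Female,75+,5.6
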