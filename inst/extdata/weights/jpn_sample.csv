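sex,age_group,share
Male,18-34,9.7
Male,35-54,15.5
Male,55-74,15.5
Male,75+,1.3
Female,18-34,12.7
Female,35-54,25.6
Female,55-74,17.7
Female,75+,2.1
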