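sex,age_group,share
Male,18-34,15.2
Male,35-54,17.2
Male,55-74,13.3
Male,75+,2.9
Female,18-34,14.5
Female,35-54,16.9
Female,55-74,14.7
Female,75+,5.3
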