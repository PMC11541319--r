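sex,age_group,share
Male,18-34,15.6
Male,35-54,17.5
Male,55-74,11.5
Male,75+,3.3
Female,18-34,15.7
Female,35-54,17.7
Female,55-74,12.7
Female,75+,6.0
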