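sex,age_group,share
Male,18-34,9.9
Male,35-54,15.9
Male,55-74,14.8
Male,75+,7.6
Female,18-34,9.5
Female,35-54,15.4
Female,55-74,15.5
Female,75+,11.4
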