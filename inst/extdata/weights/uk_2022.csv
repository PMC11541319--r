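sex,age_group,share
Male,18-34,13.8
Male,35-54,16.0
Male,55-74,14.0
Male,75+,5.1
Female,18-34,13.3
Female,35-54,16.4
Female,55-74,14.8
Female,75+,6.6
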