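gender,age_low,age_high,p25,p75
female,60,64,12,17
female,65,69,11,16
female,70,74,10,15
female,75,79,10,15
female,80,84,10,15
female,85,89,8,13
female,90,94,4,11
male,60,64,14,19
male,65,69,12,18
male,70,74,12,17
male,75,79,11,17
male,80,84,10,15
male,85,89,8,14
male,90,94,7,12
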