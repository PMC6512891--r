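rater,rater_1,rater_2,rater_3,rater_4,rater_5
rater_1,100,58,38,38,58
rater_2,58,100,25,33,75
rater_3,38,25,100,42,33
rater_4,38,33,42,100,29
rater_5,58,75,33,29,100
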