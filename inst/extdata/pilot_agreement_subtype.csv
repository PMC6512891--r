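rater,rater_1,rater_2,rater_3,rater_4,rater_5
rater_1,100,17,25,17,21
rater_2,17,100,29,29,38
rater_3,25,29,100,21,0
rater_4,17,29,21,100,50
rater_5,21,38,0,50,100
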