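rater,full,restricted,blunt,flat
rater_1,4.1,25,50,20.8
rater_2,0,12.5,66.6,20.8
rater_3,16.6,41.6,25,16.6
rater_4,8.33,50,37.5,4.16
rater_5,4.16,12.5,54.16,29.16
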