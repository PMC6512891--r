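rater,dysphoric,euthymic,manic
rater_1,0,100,0
rater_2,12.5,70.8,16.6
rater_3,54.1,41.6,4.17
rater_4,4.16,87.5,8.33
rater_5,8.33,91.66,0
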