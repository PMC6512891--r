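rater,domain,accuracy_pct
rater_2,quality,75.0
rater_3,quality,79.1
rater_4,quality,91.6
rater_5,quality,91.6
rater_1,range,75.0
rater_2,range,75.0
rater_3,range,50.0
rater_4,range,70.8
rater_5,range,70.8
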