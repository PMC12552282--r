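item_id,rater_id,score
case01,r1,5
case01,r2,5
case01,r3,5
case02,r1,4
case02,r2,4
case02,r3,5
case03,r1,5
case03,r2,5
case03,r3,4
case04,r1,3
case04,r2,3
case04,r3,3
case05,r1,4
case05,r2,5
case05,r3,4
case06,r1,5
case06,r2,5
case06,r3,5
case07,r1,2
case07,r2,3
case07,r3,2
case08,r1,4
case08,r2,4
case08,r3,4
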