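pair_id,zygosity,sex_t1,sex_t2,age_16m,age_5y,age_12y,eoe_t1_16m,eoe_t2_16m,eoe_t1_5y,eoe_t2_5y,eoe_t1_12y,eoe_t2_12y
p1,MZ,M,M,15.9,5.1,12.5,1.33,1.67,2,1.75,,
p2,DZ,M,F,15.7,5.2,,2.33,2,1.5,1.25,,
p3,DZ,F,F,15.8,,12.7,3,2.67,,,1.75,2.25
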