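time_h,cat_1,cat_2,cat_3,cat_4,cat_5,cat_6,cat_7,cat_8,cat_9,cat_10,cat_11,cat_12,cat_13,cat_14
0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
1,NS,NS,NS,1.6,NS,2,2.3,NS,NS,NS,NS,1.8,1.8,NS
2,1.8,NS,NS,NS,NS,NS,NS,NS,1.9,2.6,2.4,NS,NS,2.4
4,NS,2,1.8,NS,2.2,NS,1.6,1.8,NS,NS,NS,NS,NS,NS
8,0.9,NS,NS,NS,NS,1.1,NS,0.9,NS,NS,NS,1.2,NS,0.9
12,NS,0.5,NS,NS,0.4,NS,0.4,NS,NS,0.3,NS,NS,0.4,NS
24,0.08,NS,0.1,0.2,NS,NS,NS,NS,0.3,NS,0.4,NS,NS,NS
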