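id,treatment,pre,post
S01,DMP,1389.2,1333.632
S02,DMP,1418.2,1333.108
S03,DMP,572,531.96
S04,DMP,1279.6,1177.232
S05,DMP,1034.3,951.556
S06,DMP,874.8,796.068
S07,DMP,1157.6,1053.416
S08,DMP,375.1,337.59
S09,DMP,1054.1,948.69
S10,DMP,1116.6,993.774
S11,DMP,795.1,707.639
S12,DMP,1134.8,998.624
S13,DMP,1415.1,1245.288
S14,DMP,532.1,462.927
S15,DMP,801,688.86
S16,DMP,1422,1194.48
S17,THF,1471.7,1103.775
S18,THF,352.7,257.471
S19,THF,817.5,588.6
S20,THF,928.4,659.164
S21,THF,1375.2,976.392
S22,THF,380.3,266.21
S23,THF,1485.6,1039.92
S24,THF,1430.7,987.183
S25,THF,307.2,211.968
S26,THF,868.5,590.58
S27,THF,707.3,480.964
S28,THF,1377.5,922.925
S29,THF,781.1,523.337
S30,THF,1286.8,849.288
S31,THF,1158.9,753.285
S32,THF,1254.4,790.272
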