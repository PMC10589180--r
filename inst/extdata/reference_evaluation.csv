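dataset,dice,tp,fn,fp,area_f1,included
1,0.71,2,0,0,1.00,TRUE
2,0.82,2,0,2,0.67,TRUE
3,0.62,1,0,0,1.00,TRUE
4,0.67,1,0,0,1.00,TRUE
5,0.73,3,1,0,0.86,TRUE
6,0.67,5,2,0,0.83,TRUE
7,0.82,1,0,0,1.00,TRUE
8,0.82,2,0,0,1.00,TRUE
9,0.96,1,0,0,1.00,TRUE
10,0.71,4,0,2,0.80,TRUE
11,0.92,1,0,0,1.00,TRUE
12,0.65,4,6,1,0.53,FALSE
13,0.93,1,0,0,1.00,TRUE
14,0.91,1,0,0,1.00,TRUE
15,0.89,1,0,0,1.00,TRUE
16,0.90,1,0,0,1.00,TRUE
17,0.82,1,0,0,1.00,TRUE
18,0.73,3,0,0,1.00,TRUE
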