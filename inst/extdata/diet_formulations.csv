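name,tier,maize_g,soybean_g,yeast_g,wheat_bran_g,cost
CK,high,0,100,40,60,42.32
1,medium,0,100,20,80,36.68
2,low,0,100,0,100,31.04
3,high,20,80,40,60,41.82
4,medium,20,80,20,80,36.18
5,low,20,80,0,100,30.54
6,high,40,60,40,60,41.32
7,medium,40,60,20,80,35.68
8,low,40,60,0,100,30.04
9,high,60,40,40,60,39.8
10,medium,60,40,20,80,35.15
11,low,60,40,0,100,30.04
12,high,80,20,40,60,40.32
13,medium,80,20,20,80,34.68
14,low,80,20,0,100,29.04
15,high,100,0,40,60,39.82
16,medium,100,0,20,80,34.18
17,low,100,0,0,100,28.54
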