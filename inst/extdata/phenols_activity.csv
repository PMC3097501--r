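compound,pIC50,pred_gfa,pred_gpls,test_set
1,0.538,-0.405,0.639,0
2,1.745,1.760,1.700,0
3,2.770,3.039,2.732,0
4,3.770,3.475,3.451,1
5,0.959,1.403,1.367,1
6,0.845,1.275,0.932,0
7,2.229,2.434,2.180,0
8,2.699,2.583,2.817,0
9,3.824,4.064,3.452,0
10,0.733,0.780,0.910,0
11,2.268,2.031,2.057,1
12,2.585,2.408,2.688,0
13,1.328,1.277,1.132,1
14,2.469,2.676,2.310,0
15,2.699,2.490,3.039,0
16,3.310,3.649,3.448,0
17,2.921,2.519,3.218,0
18,3.854,4.063,3.626,0
19,1.770,2.021,1.626,0
20,1.699,2.006,2.170,1
21,2.469,2.254,2.171,1
22,2.678,2.964,2.280,0
23,2.538,2.532,2.348,1
24,2.886,3.023,2.936,1
25,2.420,2.617,2.341,0
26,2.102,1.810,2.169,0
27,2.237,2.004,2.254,0
28,0.343,-0.128,0.829,0
29,1.097,1.327,0.803,0
30,1.553,2.115,0.869,0
31,1.770,2.074,1.361,0
32,1.097,1.422,0.865,0
33,0.407,-0.914,1.548,0
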