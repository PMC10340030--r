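bin,start_month,end_month,mean_tsp_billion,cull_proportion
1,10,13,99.6,0.0067
2,14,17,229.3,0.0040
3,18,21,296.0,0.0014
4,22,25,342.9,0.0041
5,26,29,366.3,0.0030
6,30,33,386.7,0.0063
7,34,37,403.8,0.0104
8,38,41,399.8,0.0162
9,42,45,415.2,0.0100
10,46,49,398.1,0.0148
11,50,53,406.5,0.0088
12,54,57,422.8,0.0215
13,58,61,450.6,0.0202
14,62,65,489.2,0.0094
15,66,69,485.6,0.0250
16,70,73,486.0,0.0200
17,74,77,469.2,0.0571
18,78,81,433.7,0.0789
19,82,85,259.4,1.0000
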