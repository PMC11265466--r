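i,j,or,lift,phi,sci,nf
1,4,0,0,0,1,1
2,3,0,0,0,1,0
3,4,1,1,1,1,1
3,7,0,0,1,1,0
3,9,0,0,1,1,0
4,5,0,0,0,1,1
4,7,0,0,0,1,1
5,7,0,0,1,1,0
6,7,1,1,1,1,1
6,8,1,1,1,1,1
8,9,0,0,1,1,1
1,17,0,0,1,1,0
3,12,1,0,1,1,0
3,17,0,0,0,1,0
6,11,1,1,1,1,1
6,16,1,0,1,1,1
8,14,0,0,1,1,1
8,18,0,0,0,0,1
3,22,1,1,1,1,0
3,27,1,1,1,1,0
4,23,1,1,1,1,1
4,24,0,0,0,0,1
10,12,0,0,0,1,0
10,13,0,0,0,1,0
10,14,1,1,1,1,1
10,16,0,1,1,1,1
10,17,0,0,0,1,0
10,18,1,1,1,1,1
11,12,0,0,0,1,0
11,17,1,1,1,1,0
12,13,1,1,1,1,0
12,17,1,1,1,1,1
14,18,0,0,0,0,1
16,18,1,1,1,0,1
10,27,1,1,0,0,0
11,26,1,1,1,1,1
12,22,1,1,1,1,1
12,23,1,1,0,0,0
12,25,1,1,0,0,0
12,27,1,1,1,1,1
13,27,1,1,1,0,1
14,25,1,1,1,0,1
15,19,1,1,1,1,1
15,20,1,1,1,1,1
15,26,1,1,1,0,1
16,26,0,1,0,0,1
17,22,1,1,1,0,0
17,23,1,1,0,0,0
17,24,1,1,0,0,1
17,26,1,1,1,0,1
17,27,1,1,1,0,1
19,20,1,1,0,0,1
19,21,0,0,0,0,1
22,27,1,1,1,0,1
23,24,1,1,1,0,1
23,27,1,1,0,0,0
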