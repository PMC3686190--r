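partition,eigenvalue
1,3.85
2,2.98
3,2.36
4,1.85
5,1.70
6,1.48
7,1.29
8,1.18
9,1.11
10,1.01
11,0.94
12,0.86
13,0.81
14,0.75
15,0.67
16,0.56
17,0.53
18,0.49
19,0.46
20,0.43
21,0.40
22,0.32
23,0.29
24,0.23
25,0.21
26,0.13
27,0.11
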