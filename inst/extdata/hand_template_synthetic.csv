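index,u,v
1,85,232
2,103,225
3,118,231
4,133,232
5,144,229
6,153,225
7,166,210
8,172,194
9,180,178
10,152,180
11,124,178
12,98,180
13,78,186
14,72,148
15,102,142
16,132,140
17,162,146
18,196,163
19,214,138
20,228,116
21,240,96
22,64,118
23,58,92
24,54,70
25,50,50
26,99,108
27,96,80
28,94,56
29,92,34
30,134,104
31,135,76
32,136,50
33,137,26
34,168,114
35,172,88
36,175,64
37,178,42
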