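haplogroup	parent	motif
L3	root
M	L3	16223
N	L3
R	N
C	M	16223,16298,16327
Z	M	16185,16223,16260,16298
D	M	16223,16362
G	M	16223
G2a	G	16223,16227,16278,16362
M9	M	16223,16234,16316
M10	M	16223,16311
M13	M	16145,16188,16223
A	N	16223,16290,16319
N9a	N	16223,16261
N1	N
N1a	N1	16147,16172,16223,16248,16355
W	N	16223,16292
X	N	16189,16223,16278
B	R	16189,16217
F	R	16249,16304
R0	R
HV	R0
H	HV
V	HV	16298
HV6	HV	16172
JT	R	16126
J	JT	16069,16126
T	JT	16126,16294
T1	T	16126,16163,16186,16189,16294
U	R
K	U	16224,16311
U5	U	16270
U5a	U5	16256,16270
U5a1	U5a	16256,16270,16399
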