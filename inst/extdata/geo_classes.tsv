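prefix	class
R0	WestEurasian
HV	WestEurasian
N1	WestEurasian
J	WestEurasian
T	WestEurasian
U	WestEurasian
K	WestEurasian
W	WestEurasian
X	WestEurasian
M	EastEurasian
C	EastEurasian
D	EastEurasian
G	EastEurasian
Z	EastEurasian
A	EastEurasian
B	EastEurasian
F	EastEurasian
N9a	EastEurasian
U2a	SouthAsian
U2b	SouthAsian
U2c	SouthAsian
U9	SouthAsian
R1	SouthAsian
R2	SouthAsian
R5	SouthAsian
R6	SouthAsian
N1d	SouthAsian
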