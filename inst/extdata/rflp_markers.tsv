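enzyme	position	diagnostic_state	haplogroup
HaeIII	663	present	A
HindII	13259	absent	C
AluI	5176	absent	D
HaeII	4830	present	G
NlaIII	4577	absent	V
BstOI	13704	absent	J
AluI	7025	absent	H
HaeII	9052	absent	K
HinfI	12308	present	U
AluI	15606	present	T
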