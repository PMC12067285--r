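21	0	1200000	A
1	60000000	62000000	B
8	18000000	19000000	C
9	5000000	5600000	D
1	70000000	70800000	E
34	10000000	10400000	F
8	30000000	31200000	G
9	22000000	22500000	H
34	2000000	2300000	I
7	40000000	45500000	J
7	0	1500000	K
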