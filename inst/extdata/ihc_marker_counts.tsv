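marker	a	b	c	d
AQP6	3	8	6	1
Parafibromin	1	10	5	2
CK7	8	3	1	6
SYNGR3	9	2	0	7
p-AKT (stromal)	5	17	0	8
p-AKT (tumor)	13	8	4	4
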