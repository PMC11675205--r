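#kind donor
#exonic 3
base	p1	p2	p3	p4	p5	p6	p7	p8	p9
A	32	60	9	0	0	60	71	6	15
C	37	13	4	0	0	2	8	6	18
G	18	14	78	100	0	35	12	82	20
T	13	13	9	0	100	3	9	6	47
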