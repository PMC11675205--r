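#kind acceptor
#exonic 2
base	p1	p2	p3	p4	p5	p6	p7	p8	p9	p10	p11	p12	p13	p14	p15	p16
A	10	10	10	10	10	10	10	10	10	10	25	3	100	0	25	30
C	35	35	35	35	35	35	35	35	35	35	26	65	0	0	15	25
G	5	5	5	5	5	5	5	5	5	5	25	2	0	100	50	25
T	50	50	50	50	50	50	50	50	50	50	24	30	0	0	10	20
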