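chr1	C	100	CHH	CA	1.000000	10	10
chr1	C	200	CHH	CA	0.800000	8	10
chr1	C	300	CHH	CA	0.700000	7	10
chr1	C	400	CHH	CA	0.600000	6	10
chr1	C	500	CHH	CA	0.500000	5	10
chr1	C	600	CHH	CA	0.400000	4	10
chr1	C	700	CHH	CA	0.300000	3	10
chr1	C	800	CHH	CA	0.200000	2	10
chr1	C	900	CHH	CA	0.333333	1	3
chr1	C	1000	CHH	CA	0.500000	2	4
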