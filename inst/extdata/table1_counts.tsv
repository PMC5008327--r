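gene	case_with	case_without	ita1000g_with	ita1000g_without	eur1000g_with	eur1000g_without	house_with	house_without	printed_fold
BARD1	4	100	0	107	0	396	0	106	25.0
AXIN2	4	48	0	107	3	393	1	105	12.6
MC1R	5	47	5	102	3	393	3	103	5.8
CHEK2	3	49	0	107	3	393	0	106	12.5
SLC25A13	2	50	0	107	2	394	0	106	12.5
CD96	1	51	0	107	1	395	0	106	12.3
FH	1	51	0	107	0	396	1	105	12.3
XRRC3	1	51	0	107	1	395	0	106	12.3
APC	2	50	2	105	7	389	1	105	2.4
RAD50	1	51	0	107	2	394	2	104	3.0
BRCA2	1	51	1	106	3	393	1	105	2.4
SLX4	1	51	0	107	5	391	0	106	2.4
FANCM	1	51	1	106	3	393	3	103	1.7
PALB2	1	51	5	102	2	394	2	104	1.3
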