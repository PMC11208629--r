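year	E	T	SSS	SSD	NC
2017	29	35	0	2	10
2018	30	27	16	5	3
2019	17	59	6	4	22
2020	16	40	8	6	25
2021	34	22	12	6	6
2022	23	43	13	8	5
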