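gene	chrom	start_bp	end_bp
IQCA1	3	115000001	116000000
ST7	4	51000001	52000000
SND1	4	92000001	93000000
SYT1	5	8000001	9000000
AMHR2	5	26000001	27000000
DIP2B	5	29000001	30000000
VDR	5	32000001	33000000
BORCS5	5	97000001	98000000
NDUFA2	7	51000001	52000000
MOB3B	8	16000001	17000000
MPDZ	8	31000001	32000000
PEBP4	8	70000001	71000000
PDE10A	9	100000001	101000000
FOXN3	10	100000001	101000000
FSHR	11	31000001	32000000
NAV1	16	80000001	81000000
NKD1	18	18000001	19000000
ALKBH6	18	46000001	47000000
MAP3K1	20	22000001	23000000
HCN1	20	29000001	30000000
NPR3	20	40000001	41000000
SLC24A4	21	57000001	58000000
CACNA1D	22	47000001	48000000
MKRN2OS	22	56000001	57000000
RAB27B	24	54000001	55000000
TNFRSF11A	24	60000001	61000000
EDARADD	28	9000001	10000000
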