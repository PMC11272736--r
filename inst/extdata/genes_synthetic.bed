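chr1	45000000	45600000	MTOR
chr1	120000000	120400000	ARID1A
chr1	200000000	200350000	JAK1
chr2	47000000	47300000	MSH2
chr2	47800000	48100000	MSH6
chr2	190000000	190500000	ERBB4
chr3	37000000	37200000	MLH1
chr3	170000000	170800000	MECOM
chr3	178000000	178400000	PIK3CA
chr3	41000000	41250000	CTNNB1
chr4	152000000	152450000	FBXW7
chr5	1200000	1500000	TERT
chr5	68000000	68300000	PIK3R1
chr6	151000000	151600000	ESR1
chr7	5900000	6100000	PMS2
chr7	116000000	116400000	MET
chr8	55000000	55400000	SOX17
chr8	127000000	127250000	MYC
chr9	21900000	22100000	CDKN2A
chr10	87000000	87350000	PTEN
chr10	121000000	121500000	FGFR2
chr11	69000000	69300000	CCND1
chr11	108000000	108600000	ATM
chr11	2100000	2400000	HRAS
chr12	25000000	25250000	KRAS
chr12	6700000	6950000	CHD4
chr12	69200000	69450000	MDM2
chr12	132600000	132900000	POLE
chr13	48300000	48700000	RB1
chr13	32300000	32700000	BRCA2
chr14	104700000	104950000	AKT1
chr16	67600000	67850000	CTCF
chr16	2950000	3200000	ZFHX3
chr17	7500000	7700000	TP53
chr17	39600000	39900000	ERBB2
chr17	43000000	43300000	BRCA1
chr17	49100000	49350000	SPOP
chr19	30200000	30500000	CCNE1
chr19	10500000	10800000	PPP2R1A
chr20	56300000	56600000	AURKA
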