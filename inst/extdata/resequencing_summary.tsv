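population	abbrev	n_individuals	raw_bases_gb	avg_depth	n_specific_snps	n_snps
Dayu	DY	5	71	20.28	1686	6506310
Fuding	FD	16	88	7.85	4320	7521970
Xiamen	XM	18	127	10.09	1256	6868092
Zhanjiang	ZJ	16	110	9.84	9785	7382463
Zhoushan	ZS	17	131	11.00	17922	7632423
Fufa	FF	10	123	17.58	6869	7549120
Total	ALL	82	650	11.33	41838	9335807
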