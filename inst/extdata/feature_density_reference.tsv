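category	n	percent	length_mb	density_per_kb
exon	33179	7.02	43.25	0.767
intron	187807	39.74	253.78	0.740
intergenic	251560	53.24	371.65	0.677
All	472546	100.00	668.67	0.707
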