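chrom	size_mb	n_genes	mar_sg1	mar_sg5	mar_sg7
chr1	20.66	710	73	255	454
chr11	20.44	928	110	304	515
chr16	14.33	600	36	175	320
chr19	14.80	592	73	229	361
chr28	10.60	337	33	169	190
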