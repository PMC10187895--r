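# length=4640000
feature_type	name	position_bp	blocks	efficiency
oriC	oriC	3925000	.	.
dif	dif	1590000	.	.
ter	TerA	1340000	cw	1
ter	TerB	1685000	ccw	1
ter	TerG	2380000	ccw	0.5
locus	ydcM	1525000	.	.
locus	lepA	2730000	.	.
locus	qseC	3170000	.	.
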