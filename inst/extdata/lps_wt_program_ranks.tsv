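mirna_id	PicTar4way	PicTar5way	TargetScan	TargetScanS	miRanda
miR-369/3p/5p	2	4	10	1	
miR-155	5	1	7	7	
miR-374			12		2
miR-126	15	14	2	2	
miR-34/b/c		15		12	5
miR-33	20	5			8
miR-26/a	11	16	18	3	
miR-18a		9			20
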