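mirna_id	PicTar4way	PicTar5way	TargetScan	TargetScanS	miRanda
miR-126	2	2	1	1	
miR-155	3	3	6	3	
miR-33	8	6			7
miR-26/a	13			4	
miR-369/3p/5p		20	11	2	11
miR-34/b/c	19			13	14
miR-18a		15			18
miR-374			18		20
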