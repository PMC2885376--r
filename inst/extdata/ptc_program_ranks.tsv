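mirna_id	PicTar4way	PicTar5way	TargetScan	TargetScanS	miRanda
miR-222	3	2	3	4	
miR-221	6	4	2	3	
miR-346	4		5		
miR-142	7	3	10		2
miR-146				5	14
miR-144				13	6
miR-134	14		6		
miR-183	13	16	9	6	
miR-126*	20				3
miR-1				16	10
miR-206				17	11
miR-200a/b/c			18		12
miR-21	18			16	
miR-223	19			17	
miR-100				20	18
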