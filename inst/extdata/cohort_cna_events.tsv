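sample_id	sex	grade	clinical_behavior	gains	losses
CGH01	M	2b	recurrence;death	3p;5;8;14q;19p	11p
CGH02	M	2b->3	recurrence;metastasis;death	1q;3p;8q;9;14q;19p	1q;11
CGH03	M	2b->3	recurrence;metastasis;death	1q;5;15q;19p	11;17p
CGH04	F	2b	recurrence	4q	1p;11p
CGH05	F	2b->3	recurrence;metastasis;death	1q;8q;15q	1;4;5q;11;13q;15;16
CGH06	F	2b	recurrence		
CGH07	M	2a	persistence	Y	
CGH08	M	2a	persistence		15q;2p
CGH09	M	1a	remission	7;9	
CGH10	M	1a	remission	8;Y	
CGH11	F	1a	remission	9	
CGH12	F	1a	remission	7p;20	13q
CGH13	F	1a	remission	9	
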