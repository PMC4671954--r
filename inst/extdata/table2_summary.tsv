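gene_id	mean_case	sd_case	se_case	n_case	mean_ctrl	sd_ctrl	se_ctrl	n_ctrl	p_printed	flag	available	provenance
DCX	11.62274	1.82978	0.33978	29	10.91179	1.54032	0.37358	17	0.18543	NA	TRUE	NA
GRAMD1B	173.15608	48.10625	8.93311	29	217.83253	40.57191	9.84013	17	0.00245	DOWN	TRUE	NA
HIPK2	270.99334	102.12731	18.96457	29	213.90735	66.42774	16.11109	17	0.04549	UP	TRUE	NA
SLC1A2	15.62593	2.33554	0.4337	29	16.00038	2.37252	0.57542	17	0.60439	NA	TRUE	NA
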