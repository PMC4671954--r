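mirna_id	gene_id	site_region	seed_length	seed_start	p_miRWalk	p_miRanda	p_RNA22	p_TargetScan
hsa-miR-665	NRXN1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-665	RPS14	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	HMGXB3	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-665	SLC1A2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	PPARGC1B	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-665	RBM22	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	GM2A	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	SLC1A2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	GRAMD1B	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	NRXN1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3916	SPARCL1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	CSNK1A1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	GRPEL2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	SPARCL1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3164	NRXN1	3UTR	6	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	DCTN4	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	G3BP1	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3916	PCYOX1L	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	SLC1A2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	GRPEL2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	RPS14	5UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-665	RPS14	3UTR	7	1	0.05	0.05	0.05	0.05
hsa-miR-513a-5p	HIPK2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3916	PPARGC1B	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	DCTN4	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	GRAMD1B	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	PCYOX1L	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	HMGXB3	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3916	HMGXB3	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	NRXN1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-909	HIPK2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-909	CSF1R	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	SLC1A2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3164	CSF1R	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3916	DCTN4	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-909	DCTN4	3UTR	7	1	0.01	0.01	0.06	0.01
hsa-miR-27a-3p	PCYOX1L	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	HMGXB3	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	CCDC69	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	CSNK1A1	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-1254	CSNK1A1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3916	SLC1A2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	CSF1R	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-909	GRAMD1B	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	DCX	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	RBM22	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-4311	PPARGC1B	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-4311	RBM22	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	DCX	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-4311	SPARCL1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	HMGXB3	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3916	GRAMD1B	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	SLC1A2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	GRAMD1B	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-665	HIPK2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	GM2A	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	CSNK1A1	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	AFAP1L1	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-1254	NRXN1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-665	GRAMD1B	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-1254	GRAMD1B	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	SPARCL1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-1254	DCTN4	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-1254	HIPK2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3164	GRPEL2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-4311	PCYOX1L	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	GRPEL2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	HMGXB3	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	G3BP1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	SLC1A2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-1254	DCX	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3916	GRPEL2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3916	GM2A	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-4311	HIPK2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-4311	HMGXB3	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3916	G3BP1	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	HIPK2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3916	HIPK2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	GM2A	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-665	PCYOX1L	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-909	CSNK1A1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	SPARCL1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	HIPK2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	NRXN1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-1254	SPARCL1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-1254	GRPEL2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3916	NRXN1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	PCYOX1L	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3164	HIPK2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-665	PPARGC1B	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-4311	GRPEL2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	DCX	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3164	G3BP1	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-909	SLC1A2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3164	GM2A	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-909	DCX	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-1254	HMGXB3	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	CSF1R	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	NRXN1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	HIPK2	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-30c-1-3p	GRAMD1B	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-1254	SLC1A2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-665	DCX	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-665	SPARCL1	3UTR	7	2	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	DCX	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3164	SPARCL1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	G3BP1	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	SPARCL1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-4311	SLC1A2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-3164	DCX	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-3916	DCX	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-1254	GM2A	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-4311	GRAMD1B	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-4311	DCX	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-1254	G3BP1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	GRAMD1B	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	PPARGC1B	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	DCTN4	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	G3BP1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27a-3p	GRPEL2	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-665	HMGXB3	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-909	CCDC69	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-909	AFAP1L1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-1254	PCYOX1L	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-4311	NRXN1	3UTR	7	1	0.01	0.01	0.01	0.01
hsa-miR-27b-3p	GM2A	3UTR	8	1	0.01	0.01	0.01	0.01
hsa-miR-513a-5p	CCDC69	3UTR	7	1	0.01	0.01	0.01	0.01
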