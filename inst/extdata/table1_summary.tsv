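gene_id	mean_case	sd_case	se_case	n_case	mean_ctrl	sd_ctrl	se_ctrl	n_ctrl	p_printed	flag	available	provenance
ABLIM3	48.59779	58.31375	10.82859	29	22.49942	4.97781	1.2073	17	0.07359	NA	TRUE	NA
AFAP1L1	12.05416	3.3277	0.61794	29	15.09705	3.75227	0.91006	17	0.00653	DOWN	TRUE	NA
ANXA6	122.24087	67.11685	12.46329	29	147.35532	52.42362	12.7146	17	0.19289	NA	TRUE	NA
ARHGEF17	147.6068	37.55099	6.97304	29	133.18229	28.94435	7.02004	17	0.18011	NA	TRUE	NA
ARSI	19.25328	3.34174	0.62055	29	20.23331	7.4089	1.79692	17	0.54062	NA	TRUE	NA
ATOX1	193.08972	81.26299	15.09016	29	211.23735	30.26857	7.34121	17	0.38248	NA	TRUE	NA
CAMK2A	32.69334	10.36123	1.92403	29	32.51296	10.37561	2.51645	17	0.95483	NA	TRUE	NA
CCDC69	63.50043	31.51593	5.85236	29	107.38927	32.08788	7.78245	17	4e-05	DOWN	TRUE	NA
CD74	38.76174	8.96062	1.66395	29	40.6401	7.54131	1.82904	17	0.47179	NA	TRUE	NA
CSF1R	79.69017	44.38093	8.24133	29	106.02755	38.34201	9.2993	17	0.04748	DOWN	TRUE	NA
CSNK1A1	59.94675	54.80374	10.1768	29	101.51224	49.24745	11.94426	17	0.01347	DOWN	TRUE	NA
DCTN4	47.74753	16.37672	3.04108	29	68.13771	18.98236	4.6039	17	0.00039	DOWN	TRUE	NA
FAT2	19.86582	3.65128	0.67803	29	20.04196	3.26452	0.79176	17	0.87047	NA	TRUE	NA
G3BP1	57.54757	22.68119	4.21179	29	83.12785	23.39945	5.6752	17	0.00069	DOWN	TRUE	NA
GLRA1	12.83507	1.82292	0.33851	29	12.48884	1.03018	0.24986	17	0.4773	NA	TRUE	NA
GM2A	36.88007	10.41824	1.96886	29	46.9379	9.92848	2.40801	17	0.00262	DOWN	TRUE	NA
GPX3	36.37417	33.64503	6.24773	29	37.93556	27.76831	6.73481	17	0.87237	NA	TRUE	NA
GRPEL2	64.30569	23.59284	4.38108	29	98.69718	30.05175	7.28862	17	9e-05	DOWN	TRUE	NA
HMGXB3	92.76827	22.19641	4.12177	29	129.66734	24.83669	6.02378	17	5e-06	DOWN	TRUE	NA
IL17B	23.57699	3.80584	0.70673	29	25.38715	2.49688	0.60558	17	0.08732	NA	TRUE	NA
IRGM	8.72469	1.41946	0.26359	29	9.03116	0.93882	0.2277	17	0.43232	NA	TRUE	NA
LOC100652758	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	NA
MIR143HG	45.98064	7.97738	1.48136	29	44.04348	5.67301	1.37591	17	0.38484	NA	TRUE	NA
MYOZ3	126.92361	34.89592	6.48001	29	138.42359	30.43793	7.38228	17	0.26498	NA	TRUE	NA
NDST1	60.03087	27.17387	5.04606	29	58.14676	23.76045	5.76275	17	0.81347	NA	TRUE	NA
PCYOX1L	117.69138	49.35714	9.16539	29	166.65525	69.23529	16.79202	17	0.0077	DOWN	TRUE	NA
PDE6A	23.06221	12.30975	2.28586	29	20.27092	2.3138	0.56118	17	0.36191	NA	TRUE	NA
PDGFRB	23.11002	7.09533	1.31757	29	23.33169	3.82961	0.92882	17	0.90605	NA	TRUE	NA
PPARGC1B	44.98414	17.74701	3.29554	29	85.30953	26.02103	6.31103	17	1e-07	DOWN	TRUE	NA
RBM22	63.53639	26.10673	4.8479	29	94.33986	17.52159	4.24961	17	9e-05	DOWN	TRUE	NA
RPS14	7856.9131	1234.65184	229.26909	29	10598.78235	941.02851	228.23294	17	6e-10	DOWN	TRUE	NA
SH3TC2	14.87956	4.13834	0.76847	29	14.6208	3.05314	0.7405	17	0.82371	NA	TRUE	NA
SLC26A2	114.135	53.33529	9.90411	29	200.29804	70.23587	17.0347	17	3e-05	DOWN	TRUE	mean_case=114135
SLC36A1	44.44143	14.114	2.6209	29	46.69696	15.60091	3.78378	17	0.61728	NA	TRUE	sd_case=14114
SLC36A3	NA	NA	NA	NA	NA	NA	NA	NA	NA	NA	FALSE	NA
SLC6A7	46.04152	6.0099	1.11601	29	47.21034	6.08871	1.47673	17	0.52959	NA	TRUE	NA
SMIM3	260.38469	141.71754	26.31629	29	500.79865	310.45128	75.2955	17	0.00081	DOWN	TRUE	NA
SPARC	49.30088	41.99314	7.79793	29	62.24083	28.91624	7.01322	17	0.26807	NA	TRUE	NA
SYNPO	110.19731	20.31167	3.77178	29	115.67666	15.80301	3.83279	17	0.34516	NA	TRUE	NA
TCOF1	57.14866	25.18242	4.67626	29	73.23271	19.88939	4.82388	17	0.02946	DOWN	TRUE	NA
TIGD6	7.45674	0.79702	0.148	29	7.39382	0.78457	0.19029	17	0.79614	NA	TRUE	se_case=148
TNIP1	139.14645	86.98013	16.1518	29	154.56547	45.26099	10.9774	17	0.50195	NA	TRUE	NA
ZNF300	96.84063	73.90228	13.72331	29	86.83198	35.88454	8.70328	17	0.60446	NA	TRUE	NA
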