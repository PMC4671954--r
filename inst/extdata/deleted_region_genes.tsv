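gene_id
ABLIM3
AFAP1L1
ANXA6
ARHGEF17
ARSI
ATOX1
CAMK2A
CCDC69
CD74
CSF1R
CSNK1A1
DCTN4
FAT2
G3BP1
GLRA1
GM2A
GPX3
GRPEL2
HMGXB3
IL17B
IRGM
LOC100652758
MIR143HG
MYOZ3
NDST1
PCYOX1L
PDE6A
PDGFRB
PPARGC1B
RBM22
RPS14
SH3TC2
SLC26A2
SLC36A1
SLC36A3
SLC6A7
SMIM3
SPARC
SYNPO
TCOF1
TIGD6
TNIP1
ZNF300
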