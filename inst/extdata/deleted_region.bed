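chr5	131000000	139000000	5q_CDR	0	.
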