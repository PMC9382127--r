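gene_a	gene_b	classification
AcPRX59	AcPRX16	segmental
AcPRX58	AcPRX46	segmental
AcPRX46	AcPRX15	segmental
AcPRX59	AcPRX15	segmental
AcPRX30	AcPRX12	segmental
AcPRX32	AcPRX37	segmental
AcPRX30	AcPRX37	segmental
AcPRX22	AcPRX41	segmental
AcPRX20	AcPRX18	segmental
AcPRX33	AcPRX9	segmental
AcPRX48	AcPRX20	segmental
AcPRX51	AcPRX4	segmental
AcPRX27	AcPRX6	segmental
AcPRX62	AcPRX26	segmental
AcPRX23	AcPRX1	segmental
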