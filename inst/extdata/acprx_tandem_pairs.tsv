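gene_a	gene_b	classification
AcPRX2	AcPRX3	tandem
AcPRX2	AcPRX4	tandem
AcPRX3	AcPRX4	tandem
AcPRX7	AcPRX8	tandem
AcPRX10	AcPRX11	tandem
AcPRX14	AcPRX15	tandem
AcPRX14	AcPRX16	tandem
AcPRX18	AcPRX19	tandem
AcPRX18	AcPRX20	tandem
AcPRX18	AcPRX21	tandem
AcPRX19	AcPRX20	tandem
AcPRX19	AcPRX21	tandem
AcPRX20	AcPRX21	tandem
AcPRX40	AcPRX41	tandem
AcPRX55	AcPRX56	tandem
AcPRX58	AcPRX59	tandem
AcPRX68	AcPRX69	tandem
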