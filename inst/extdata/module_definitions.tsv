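#gotcells tsv schema=1 bundled module gene lists
set_name	gene
hla_class_ii	HLA-DRA
hla_class_ii	HLA-DRB1
hla_class_ii	HLA-DRB5
hla_class_ii	HLA-DQA1
hla_class_ii	HLA-DQA2
hla_class_ii	HLA-DQB1
hla_class_ii	HLA-DMA
hla_class_ii	HLA-DMB
hla_class_ii	HLA-DPA1
hla_class_ii	HLA-DPB1
s100a_alarmins	S100A8
s100a_alarmins	S100A9
s100a_alarmins	S100A12
exhaustion	CXCL13
exhaustion	HAVCR2
exhaustion	PDCD1
exhaustion	TIGIT
exhaustion	LAG3
exhaustion	CTLA4
exhaustion	LAYN
exhaustion	RBPJ
exhaustion	VCAM1
exhaustion	GZMB
exhaustion	TOX
exhaustion	MYO7A
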