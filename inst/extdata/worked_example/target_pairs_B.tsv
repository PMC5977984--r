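mirna_id	gene_id
miR-001	GENE001
miR-001	GENE002
miR-001	GENE003
miR-001	GENE004
miR-002	GENE005
miR-002	GENE006
miR-002	GENE007
miR-001	GENE010
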