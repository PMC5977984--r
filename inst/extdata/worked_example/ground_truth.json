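{"planted":{"mirna_id":["miR-001","miR-002"],"delta":[1.5,-1.5]},"truePairs":{"mirna_id":["miR-001","miR-001","miR-001","miR-001","miR-002","miR-002","miR-002"],"gene_id":["GENE001","GENE002","GENE003","GENE004","GENE005","GENE006","GENE007"]},"bridge":["GENE001","GENE005"],"modules":{"gene_id":["GENE001","GENE002","GENE003","GENE004","GENE005","GENE006","GENE007"],"module":[1,1,1,1,2,2,2]}}
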