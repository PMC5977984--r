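gene_a	gene_b	combined_score
GENE001	GENE002	0.888947719009593
GENE001	GENE003	0.762592840229627
GENE001	GENE004	0.715787439525593
GENE001	GENE005	0.680044452042785
GENE002	GENE003	0.850348932901397
GENE002	GENE004	0.702373113844078
GENE003	GENE004	0.578794359229505
GENE005	GENE006	0.697278170031495
GENE005	GENE007	0.611219431622885
GENE006	GENE007	0.766343974357005
GENE008	GENE009	0.253479910711758
GENE008	GENE010	0.399117382697295
GENE008	GENE011	0.449103320005815
GENE008	GENE012	0.430652943602763
GENE009	GENE010	0.316629847034346
GENE009	GENE011	0.255615313234739
GENE009	GENE012	0.253690639615525
GENE010	GENE011	0.333165374223609
GENE010	GENE012	0.290088211582042
GENE011	GENE012	0.392816928203683
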