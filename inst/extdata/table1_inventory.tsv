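gene_family	species	identifier	class_label	isoform_count
eIF4E-1/2	D. melanogaster	CG4035	I	2
eIF4E-1/2	D. simulans	GD12928	I	1
eIF4E-1/2	D. sechellia	GM24878	I	1
eIF4E-1/2	D. erecta	GG14044	I	1
eIF4E-1/2	D. yakuba	GE21247	I	1
eIF4E-1/2	D. ananassae	GF23736	I	1
eIF4E-1/2	D. willistoni	GK20927	I	1
eIF4E-1/2	D. pseudoobscura	GA28658	I	1
eIF4E-1/2	D. persimilis	GL12850	I	1
eIF4E-1/2	D. virilis	GJ13832	I	1
eIF4E-1/2	D. grimshawi	GH16860	I	1
eIF4E-1/2	A. aegypti	AAEL001916	I	1
eIF4E-1/2	A. gambiae	AGAP007172	I	1
eIF4E-1/2	C. floridanus	EFN73765	I	1
eIF4E-1/2	H. saltator	EFN83757	I	1
eIF4E-1/2	A. mellifera	XP_624290.2	I	1
eIF4E-1/2	T. castaneum	XP_973494	I	1
eIF4E-1/2	M. sexta	MSP00767	I	1
eIF4E-1/2	S. frugiperda	AAK94897	I	1
eIF4E-1/2	B. mori	BGIBMGA012674	I	1
eIF4E-1/2	H. melpomene	HMP00347	I	1
eIF4E-1/2	A. pisum	ACYPI001956	I	1
eIF4E-3	D. melanogaster	CG8023	I	1
eIF4E-3	D. simulans	GD14067	I	1
eIF4E-3	D. sechellia	GM25034	I	1
eIF4E-3	D. erecta	GG14292	I	1
eIF4E-3	D. yakuba	GE20721	I	1
eIF4E-3	D. ananassae	GF25106	I	1
eIF4E-3	D. willistoni	GK17185	I	1
eIF4E-3	D. pseudoobscura	GA24628	I	1
eIF4E-3	D. persimilis	GL26506	I	1
eIF4E-3	D. virilis	GJ12520	I	1
eIF4E-3	D. grimshawi	GH15498	I	1
eIF4E-4	D. melanogaster	CG10124	I	1
eIF4E-4	D. simulans	GD13118	I	1
eIF4E-4	D. sechellia	GM13832	I	1
eIF4E-4	D. erecta	GG15032	I	1
eIF4E-4	D. yakuba	GE20475	I	1
eIF4E-4	D. ananassae	GF10894	I	1
eIF4E-4	D. willistoni	GK12583	I	1
eIF4E-4	D. pseudoobscura	GA28599	I	1
eIF4E-4	D. persimilis	GL13241	I	1
eIF4E-4	D. virilis	GJ12668	I	1
eIF4E-4	D. grimshawi	GH15637	I	1
eIF4E-4	D. mojavensis	GI12684	I	1
eIF4E-5	D. melanogaster	CG8277	I	1
eIF4E-5	D. simulans	GD14038	I	1
eIF4E-5	D. sechellia	GM25004	I	1
eIF4E-5	D. erecta	GG14453	I	1
eIF4E-5	D. yakuba	GE21642	I	1
eIF4E-5	D. ananassae	GF10327	I	1
eIF4E-5	D. willistoni	GK17737	I	1
eIF4E-5	D. pseudoobscura	GA28380	I	1
eIF4E-5	D. persimilis	GL18042	I	1
eIF4E-5	D. virilis	GJ13889	I	1
eIF4E-5	D. grimshawi	GH14978	I	1
eIF4E-5	D. mojavensis	GI13141	I	1
eIF4E-6	D. melanogaster	CG1442	I	1
eIF4E-6	D. simulans	GD18002	I	1
eIF4E-6	D. sechellia	GM12271	I	1
eIF4E-6	D. erecta	GG12044	I	1
eIF4E-6	D. yakuba	GE10483	I	1
eIF4E-7	D. melanogaster	CG32859	I	1
eIF4E-7	D. simulans	GD16435	I	1
eIF4E-7	D. sechellia	GM18997	I	1
eIF4E-7	D. erecta	GG12718	I	1
eIF4E-7	D. yakuba	GE16544	I	1
eIF4E-7	D. ananassae	GF22031	I	1
eIF4E-7	D. willistoni	GK16243	I	1
eIF4E-7	D. virilis	GJ16331	I	1
eIF4E-7	D. mojavensis	GI14982	I	1
4E-HP	D. melanogaster	CG33100	II	1
4E-HP	D. simulans	GD18325	II	1
4E-HP	D. sechellia	GM23515	II	1
4E-HP	D. erecta	GG12377	II	1
4E-HP	D. yakuba	GE10831	II	1
4E-HP	D. ananassae	GF23230	II	1
4E-HP	D. willistoni	GK11937	II	1
4E-HP	D. pseudoobscura	GA26519	II	1
4E-HP	D. persimilis	GL24147	II	1
4E-HP	D. virilis	GJ14537	II	1
4E-HP	D. grimshawi	GH19097	II	1
4E-HP	D. mojavensis	GI23433	II	1
4E-HP	A. aegypti	AAEL005796	II	1
4E-HP	A. gambiae	AGAP002948	II	1
4E-HP	T. castaneum	XP_970157	II	1
4E-HP	B. mori	NP_001091833	II	1
4E-HP	P. xuthus	BAG30778	II	1
4E-HP	A. pisum	ACYPI000423	II	1
4E-HP	C. floridanus	EFN65857	II	1
4E-HP	N. vitripennis	XP_003426016	II	1
4E-HP	A. mellifera	XP_623570	II	1
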