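subset_id	ighv_genes	cdr3_length	consensus_cdr3	motif	motif_offset	mutation_class	light_chain_gene
T1	IGHV1-69,IGHV1-2	13	ARDKGYYDSWFDP	KGYY	3	U	NA
T2	IGHV3-21,IGHV3-23	9	ARDANGMDV	NGMD	4	M	IGLV3-21
T3	IGHV4-34,IGHV4-39	16	ARGYGDYWGSYRFDYY	WGXYR	7	M	IGKV2-30
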