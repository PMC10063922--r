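subset_id	ighv_genes	cdr3_length	consensus_cdr3	motif	motif_offset	mutation_class	light_chain_gene	provenance
1	IGHV1-69	14	ARDNWDYSSGYFDY	NWDY	3	U	NA	genes+class literature; consensus+motif SYNTHETIC placeholders
2	IGHV3-21	9	ARDDPSGDY	DPSG	3	M	IGLV3-21	genes+class+light literature; consensus+motif SYNTHETIC placeholders
4	IGHV4-34	16	ARDGYGDYYYYYGMDV	GYGD	3	M	IGKV2-30	genes+class+light literature; consensus+motif SYNTHETIC placeholders
8	IGHV4-39	19	ARDGGYYDSSGYYYYFDYW	GGYY	3	U	NA	genes+class literature; consensus+motif SYNTHETIC placeholders
12	IGHV1-69	11	ARDWDYRGMDV	WDYR	3	U	NA	class literature; gene+consensus+motif SYNTHETIC placeholders
14	IGHV4-4	12	ARDSGYSYGMDV	SGYS	3	M	NA	genes+class literature; consensus+motif SYNTHETIC placeholders
28A	IGHV1-2	13	ARDYDFWSGYFDY	YDFW	3	U	NA	genes+class literature; consensus+motif SYNTHETIC placeholders
31	IGHV3-48	12	ARDVGATYGMDV	VGAT	3	U	NA	class literature; gene+consensus+motif SYNTHETIC placeholders
59	IGHV1-58	10	ARDKGDYFDY	KGDY	3	U	NA	class literature; gene+consensus+motif SYNTHETIC placeholders
73	IGHV3-23	15	ARDDSSGYYYYGMDV	DSSG	3	M	NA	class literature; gene+consensus+motif SYNTHETIC placeholders
77	IGHV4-34	17	ARDYSGYDSSGYYYFDY	YSGY	3	M	IGLV10-54	genes+class+light literature; consensus+motif SYNTHETIC placeholders
148B	IGHV2-5	11	ARDLGVYGMDV	LGVY	3	M	NA	genes+class literature; consensus+motif SYNTHETIC placeholders
169	IGHV3-21	9	ARDDPSRDY	DPSR	3	M	IGLV3-21	genes+class+light literature; consensus+motif SYNTHETIC placeholders
201	IGHV4-34	14	ARDGSGSYYYGMDV	GSGS	3	M	IGLV1-44	genes+class+light literature; consensus+motif SYNTHETIC placeholders
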