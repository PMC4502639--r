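entrez_id	gene_symbol	gene_name	K	GS	f
11335	CBX3	chromobox homolog 3	0.82	0.43	982
5723	PSPH	phosphoserine phosphatase	0.37	0.32	980
27032	ATP2C1	ATPase, Ca++ transporting, type 2C, member 1	0.91	0.40	948
29887	SNX10	sorting nexin 10	0.72	0.38	936
23531	MMD	monocyte to macrophage differentiation-associated	0.57	0.37	936
79572	ATP13A3	ATPase type 13A3	0.74	0.38	929
2744	GLS	glutaminase	0.70	0.37	923
1956	EGFR	epidermal growth factor receptor	0.63	0.33	869
2768	GNA12	guanine nucleotide binding protein (G protein) alpha 12	0.80	0.37	840
10257	ABCC4	ATP-binding cassette, sub-family C (CFTR/MRP), member 4	0.46	0.32	770
3149	HMGB3	high mobility group box 3	0.74	0.36	765
8091	HMGA2	high mobility group AT-hook 2	0.81	0.34	744
3198	HOXA1	homeobox A1	0.75	0.34	676
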