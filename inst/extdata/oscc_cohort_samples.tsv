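dataset	tumor_initial	normal_initial	tumor_after_qc	normal_after_qc	platform
GSE31056	23	24	23	24	HGU-133plus2
GSE9844	26	12	26	12	HGU-133plus2
GSE30784	167	45	165	45	HGU-133plus2
GSE3524	16	4	16	4	HGU-133a
GSE42743	74	29	73	27	HGU-133plus2
GSE2280	22	5	22	5	HGU-133a
GSE6791	30	14	30	14	HGU-133plus2
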