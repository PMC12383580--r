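# Default 18-SNP cardiometabolic panel.
# Risk alleles are CONFIGURATION curated from the external GWAS /
# nutrigenetics literature (the allele counted 0/1/2 per genotype); they are
# not measured data and should be reviewed before use on real cohorts.
rsid	gene	risk_allele	ref	alt
rs4343	ACE	G	A	G
rs283411	ADH1C	T	C	T
rs5751876	ADORA2A	T	C	T
rs1042713	ADRB2	A	G	A
rs5128	APOC3	G	C	G
rs429358	APOE	C	T	C
rs7412	APOE	C	C	T
rs1801260	CLOCK	C	T	C
rs762551	CYP1A2	C	A	C
rs174570	FADS2	T	C	T
rs9930506	FTO	G	A	G
rs9939609	FTO	A	T	A
rs1800588	LIPC	T	C	T
rs17782313	MC4R	C	T	C
rs4988235	MCM6	G	G	A
rs5400	SLC2A2	T	C	T
rs12255372	TCF7L2	T	G	T
rs7903146	TCF7L2	T	C	T
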