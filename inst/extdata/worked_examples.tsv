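# Calibration set: published 21-nt promoter contexts with in silico Kd
# estimates (nM) for the ancestral and minor alleles of two human genes,
# embedded at their published TSS-relative positions in a 90-nt promoter
# whose flanks are a fixed neutral poly-C pad (no TATA-like windows, zero
# sliding/bending contribution). The SNP sits at position -28 (CRP-201)
# and -60 (SERPINF1-205); the padded context occupies -38..-18 (CRP) and
# -70..-50 (SERPINF1). The allele column marks the substituted base.
id	gene	transcript	allele	snp_position	sequence	kd_nM	se_nM
CRP_norm	CRP	CRP-201	norm	-28	cccccccccccccccccccccccccccccccccccccccccccccccccccctgctttggatataaatccaggccccccccccccccccc	2.26	0.23
CRP_rs1660782480_G	CRP	CRP-201	G	-28	cccccccccccccccccccccccccccccccccccccccccccccccccccctgctttggatgtaaatccaggccccccccccccccccc	7.64	0.76
CRP_rs1660782424_C	CRP	CRP-201	C	-28	cccccccccccccccccccccccccccccccccccccccccccccccccccctgctttggatacaaatccaggccccccccccccccccc	6.19	0.62
SERPINF1_norm	SERPINF1	SERPINF1-205	norm	-60	ccccccccccccccccccccgagtgcaggtcgctttaagaaccccccccccccccccccccccccccccccccccccccccccccccccc	10.21	0.92
SERPINF1_rs541151948_A	SERPINF1	SERPINF1-205	A	-60	ccccccccccccccccccccgagtgcaggtagctttaagaaccccccccccccccccccccccccccccccccccccccccccccccccc	7.27	0.51
SERPINF1_rs541151948_T	SERPINF1	SERPINF1-205	T	-60	ccccccccccccccccccccgagtgcaggttgctttaagaaccccccccccccccccccccccccccccccccccccccccccccccccc	8.53	0.77
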