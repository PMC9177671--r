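# Genic SNPs reported in the CcLG03 days-to-flowering candidate region (pigeonpea ICP 5529 x ICP 11605 F2 QTL-seq; high bulk = late-flowering pool, low bulk = early-flowering pool)
# coordinates: 1-based inclusive; codons shown with the variant base upper-cased
chrom	gene	pos	ref	high_allele	snp_index_high	low_allele	snp_index_low	delta	snp_effect	codon_ref	codon_alt	annotation
CcLG03	C.cajan_09900	19222701	G	G	0	A	1	-1	Exon (nsSNP)	aCg	aTg	Pentatricopeptide repeat-containing protein
CcLG03	C.cajan_09938	19549631	A	A	0	G	1	-1	Intron	NA	NA	Chromodomain-helicase-DNA-binding protein 4
CcLG03	C.cajan_09958	19690312	G	G	0	A	1	-1	Intron	NA	NA	Maestro heat-like repeat-containing protein family
CcLG03	C.cajan_09965	19763754	C	C	0	T	1	-1	Intron	NA	NA	Phosphatidylinositol 4-phosphate 5-kinase 9
CcLG03	C.cajan_10046	20439904	G	G	0	C	1	-1	Intron	NA	NA	1,4-alpha-glucan-branching enzyme
CcLG03	C.cajan_10067	20635496	T	T	0	A	1	-1	Intron	NA	NA	Uridine nucleosidase 1
CcLG03	C.cajan_10078	20745506	G	G	0	T	1	-1	Exon (sSNP)	NA	NA	Cell division protein
CcLG03	C.cajan_10078	20745771	A	A	0	G	1	-1	Intron	NA	NA	Cell division protein
CcLG03	C.cajan_10078	20747419	C	C	0	T	1	-1	Intron	NA	NA	Cell division protein
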