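# Genic SNPs reported in the CcLG08 leaf-shape candidate region (pigeonpea ICP 5529 x ICP 11605 F2 QTL-seq; high bulk = obcordate pool, low bulk = lanceolate pool)
# coordinates: 1-based inclusive; codons shown with the variant base upper-cased
# one source row prints a truncated delta ("-") at C.cajan_16013:7068679; transcribed as -1 (its indices are 0 and 1, like every other row)
chrom	gene	pos	ref	high_allele	snp_index_high	low_allele	snp_index_low	delta	snp_effect	codon_ref	codon_alt	annotation
CcLG08	C.cajan_15985	6701814	A	A	0	T	1	-1	Intron	NA	NA	Beta-carotene hydroxylase 2
CcLG08	C.cajan_15991	6764651	T	T	0	C	1	-1	Exon (nsSNP)	Tgt	Cgt	Ac-like transposase
CcLG08	C.cajan_16002	6915910	T	T	0	C	1	-1	Exon (nsSNP)	aTg	aCg	Uncharacterized protein
CcLG08	C.cajan_16003	6921340	A	A	0	G	1	-1	Exon (sSNP)	NA	NA	Pro-Pol polyprotein
CcLG08	C.cajan_16003	6923929	T	T	0	C	1	-1	Intron	NA	NA	Pro-Pol polyprotein
CcLG08	C.cajan_16003	6924854	A	A	0	G	1	-1	Intron	NA	NA	Pro-Pol polyprotein
CcLG08	C.cajan_16003	6927480	C	C	0	T	1	-1	Intron	NA	NA	Pro-Pol polyprotein
CcLG08	C.cajan_16003	6927533	A	A	0	G	1	-1	Intron	NA	NA	Pro-Pol polyprotein
CcLG08	C.cajan_16003	6927560	T	T	0	C	1	-1	Intron	NA	NA	Pro-Pol polyprotein
CcLG08	C.cajan_16003	6927678	T	T	0	C	1	-1	Intron	NA	NA	Pro-Pol polyprotein
CcLG08	C.cajan_16012	7057478	G	G	0	A	1	-1	Exon (nsSNP)	Gca	Aca	F-box protein
CcLG08	C.cajan_16012	7059171	T	T	0	C	1	-1	Intron	NA	NA	F-box protein
CcLG08	C.cajan_16013	7068488	G	G	0	C	1	-1	Intron	NA	NA	Uncharacterized protein
CcLG08	C.cajan_16013	7068679	G	G	0	A	1	-1	Intron	NA	NA	Uncharacterized protein
CcLG08	C.cajan_16013	7070780	C	C	0	T	1	-1	Exon (nsSNP)	cCt	cTt	Uncharacterized protein
CcLG08	C.cajan_16014	7083922	T	T	0	A	1	-1	Intron	NA	NA	Transcriptional corepressor
CcLG08	C.cajan_16014	7093751	G	G	0	A	1	-1	Intron	NA	NA	Transcriptional corepressor
CcLG08	C.cajan_16038	7456634	T	T	0	C	1	-1	Intron	NA	NA	Cytochrome P450
CcLG08	C.cajan_16038	7456764	A	A	0	G	1	-1	Intron	NA	NA	Cytochrome P450
CcLG08	C.cajan_16038	7456831	T	T	0	A	1	-1	Intron	NA	NA	Cytochrome P450
CcLG08	C.cajan_16038	7456974	A	A	0	G	1	-1	Intron	NA	NA	Cytochrome P450
CcLG08	C.cajan_16038	7457844	C	C	0	A	1	-1	Intron	NA	NA	Cytochrome P450
CcLG08	C.cajan_16041	7486941	A	A	0	G	1	-1	Intron	NA	NA	Uncharacterized protein
CcLG08	C.cajan_16047	7606346	T	T	0	A	1	-1	Intron	NA	NA	Transposon Ty3-I
CcLG08	C.cajan_16049	7641790	A	A	0	C	1	-1	Intron	NA	NA	E3 ubiquitin-protein ligase
CcLG08	C.cajan_16049	7642733	G	G	0	A	1	-1	Intron	NA	NA	E3 ubiquitin-protein ligase
CcLG08	C.cajan_16049	7643315	A	A	0	C	1	-1	Exon (sSNP)	NA	NA	E3 ubiquitin-protein ligase
CcLG08	C.cajan_16051	7666784	A	A	0	G	1	-1	Intron	NA	NA	Protein ROOT PRIMORDIUM DEFECTIVE 1
CcLG08	C.cajan_16051	7667174	T	T	0	C	1	-1	Intron	NA	NA	Protein ROOT PRIMORDIUM DEFECTIVE 1
CcLG08	C.cajan_16059	7780600	A	A	0	T	1	-1	Intron	NA	NA	Probable methyltransferase PMT16
CcLG08	C.cajan_16061	7838639	C	C	0	T	1	-1	Exon (sSNP)	NA	NA	1-aminocyclopropane-1-carboxylate oxidase homolog 1
CcLG08	C.cajan_16062	7870949	A	A	0	G	1	-1	Intron	NA	NA	Uncharacterized protein
CcLG08	C.cajan_16063	7888623	G	G	0	A	1	-1	Intron	NA	NA	1-aminocyclopropane-1-carboxylate oxidase homolog 12
CcLG08	C.cajan_16066	7940765	C	C	0	G	1	-1	Intron	NA	NA	Tripeptidyl-peptidase 2
CcLG08	C.cajan_16066	7947009	G	G	0	A	1	-1	Intron	NA	NA	Tripeptidyl-peptidase 2
CcLG08	C.cajan_16066	7950673	A	A	0	C	1	-1	Intron	NA	NA	Tripeptidyl-peptidase 2
CcLG08	C.cajan_16068	8008253	C	C	0	A	1	-1	Intron	NA	NA	Cytochrome P450
CcLG08	C.cajan_16074	8168767	C	C	0	A	1	-1	Intron	NA	NA	Type I inositol
CcLG08	C.cajan_16099	8666995	T	T	0	C	1	-1	Exon (sSNP)	NA	NA	-
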