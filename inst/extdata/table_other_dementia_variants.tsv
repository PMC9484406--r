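gene	patient_id	fh_score	hgvs_c	hgvs_p	zygosity	clinvar_class	conflicting_detail	hgmd_phenotype	prediction	gnomad_nfe	app_exon	literature_flags	reported_significance
CCNF	AD#020	0	c.353T>C	p.Val118Ala	HET	NR	.	NR	likely_pathogenic	1/111550	.	.	.
CCNF	AD#079	1.5	c.656T>C	p.Leu219Pro	HET	NR	.	NR	likely_pathogenic	5/111832	.	.	.
CHCHD10	AD#068	0	c.354C>A	p.Asp118Glu	HET	VUS	.	NR	.	NR	.	.	.
CSF1R	AD#081	0	c.1400C>T	p.Thr467Met	HET	NR	.	NR	likely_benign	5/113734	.	.	.
CSF1R	AD#057	3.5	c.1477A>G	p.Ser493Gly	HET	NR	.	NR	likely_benign	NR	.	.	.
CSF1R	AD#044	0	c.2850C>A	p.His950Gln	HET	NR	.	NR	likely_benign	2/113066	.	.	.
CSF1R	AD#044	0	c.2851C>A	p.Leu951Met	HET	NR	.	NR	likely_benign	2/113102	.	.	.
DCTN1	AD#102	3.5	c.586A>G	p.Ile196Val	HET	Conflicting	uncertain:2;benign:6	abnormal cellular organization	.	649/105456	.	.	.
DCTN1	AD#030	0	c.1361T>C	p.Val454Ala	HET	NR	.	NR	likely_pathogenic	NR	.	.	.
DCTN1	AD#100	3	c.1480G>A	p.Ala494Thr	HET	VUS	.	amyotrophic lateral sclerosis, phenotype modifiers?	.	4/128890	.	.	.
DCTN1	AD#067	0	c.1555A>G	p.Lys519Glu	HET	NR	.	NR	likely_pathogenic	NR	.	.	.
DCTN1	AD#070	1	c.2278A>G	p.Met760Val	HET	Conflicting	uncertain:2;benign:2;likely_benign:1	NR	.	10/129140	.	.	.
DCTN1	AD#078	0	c.2989C>T	p.Arg997Trp	HET	VUS	.	amyotrophic lateral sclerosis	.	1/113370	.	.	.
FIG4	AD#080	0	c.2200G>A	p.Glu734Lys	HET	VUS	.	NR	.	15/113494	.	.	.
FIG4	AD#097	0	c.2467C>T	p.Gln823Ter	HOM_ALT	Pathogenic	.	NR	.	7/129138	.	.	.
FUS	AD#039	0	c.430_447del	p.Gly144_Tyr149del	HET	Conflicting	pathogenic:1;likely_pathogenic:1;uncertain:1	NR	.	10/113750	.	.	.
FUS	AD#033	1.5	c.681_686del	p.Gly230_Gly231del	HET	Conflicting	benign:1;uncertain:1	NR	.	56/117710	.	.	.
FUS	AD#049	3.5	c.681_686del	p.Gly230_Gly231del	HET	Conflicting	benign:1;uncertain:1	NR	.	56/117710	.	.	.
MAPT	AD#039	0	c.121G>A	p.Ala41Thr	HET	VUS	.	Alzheimer disease?	.	6/128512	.	.	.
MAPT	AD#017	3.5	c.454G>A	p.Ala152Thr	HET	Conflicting	uncertain:2;benign:1;likely_benign:2	neurodegeneration	.	297/129002	.	.	.
NOTCH3	AD#085	0	c.1505C>T	p.Ser502Phe	HET	VUS	.	NR	.	9/75540	.	.	.
NOTCH3	AD#071	3	c.3315C>T	p.Gly1105=	HET	NR	.	NR	likely_benign	1/113330	.	.	.
NOTCH3	AD#099	0	c.3535A>G	p.Asn1179Asp	HET	NR	.	NR	likely_pathogenic	NR	.	.	.
NOTCH3	AD#074	3.5	c.4461C>T	p.Gly1487=	HET	NR	.	NR	likely_benign	NR	.	.	.
NOTCH3	AD#093	3.5	c.5816-6C>T	.	HET	NR	.	NR	likely_benign	6/113474	.	.	.
OPTN	AD#010	3.5	c.448C>T	p.Leu150=	HET	NR	.	NR	likely_benign	7/129170	.	.	.
OPTN	AD#091	3.5	c.941A>T	p.Gln314Leu	HET	Conflicting	pathogenic:1;uncertain:1	amyotrophic lateral sclerosis	.	38/129076	.	.	.
OPTN	AD#069	0	c.1401+4A>G	.	HET	VUS	.	amyotrophic lateral sclerosis	.	17/129180	.	.	.
OPTN	AD#053	0	c.1643G>A	p.Arg548Gln	HET	VUS	.	NR	.	9/129122	.	.	.
SQSTM1	AD#066	0	c.315C>T	p.Cys105=	HET	NR	.	NR	likely_benign	NR	.	.	.
SQSTM1	AD#092	3.5	c.960G>A	p.Gly320=	HET	NR	.	NR	likely_benign	1/81718	.	.	.
SQSTM1	AD#032	3.5	c.1175C>T	p.Pro392Leu	HET	Conflicting	pathogenic:4;likely_pathogenic:1;uncertain:2;benign:1	paget disease of bone	.	173/128718	.	.	.
TYROBP	AD#077	0	c.140T>C	p.Val47Ala	HET	VUS	.	Alzheimer disease, early onset?	.	14/128556	.	.	.
UBQLN2	AD#095	0	c.1461C>A	p.Thr487=	HET	Conflicting	uncertain:1;benign:5;likely_benign:1	NR	.	787/87391	.	.	.
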