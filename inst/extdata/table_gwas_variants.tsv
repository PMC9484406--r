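gene	patient_id	fh_score	hgvs_c	hgvs_p	zygosity	clinvar_class	conflicting_detail	hgmd_phenotype	prediction	gnomad_nfe	app_exon	literature_flags	reported_significance
ADAM10	AD#060	0	c.112A>G	p.Asn38Asp	HET	NR	.	NR	likely_benign	NR	.	.	.
ADAM10	AD#065	3.5	c.556dupC	p.Gln186ProfsTer19	HET	NR	.	NR	likely_pathogenic	NR	.	.	.
BIN1	AD#095	0	c.696C>A	p.Asn232Lys	HET	VUS	.	NR	.	98/129022	.	.	.
BIN1	AD#009	0	c.865G>A	p.Ala289Thr	HET	NR	.	NR	likely_benign	3/94156	.	.	.
BIN1	AD#082	0	c.1462-3C>T	.	HET	VUS	.	NR	.	16/128710	.	.	.
CLU	AD#096	0	c.509C>T	p.Thr170Met	HET	NR	.	NR	likely_benign	2/113698	.	.	.
CR1	AD#062	0	c.4956G>A	p.Pro1652=	HET	NR	.	NR	likely_benign	NR	.	.	.
CR1	AD#075	0	c.4356T>C	p.Cys1452=	HET	NR	.	NR	likely_benign	1084/128002	.	.	.
ELAVL1	AD#010	3.5	c.765C>T	p.Ala255=	HET	NR	.	NR	likely_benign	29/129192	.	.	.
EP300	AD#098	0	c.2194C>T	p.Pro732Ser	HET	NR	.	NR	likely_pathogenic	NR	.	.	.
EPHA1	AD#010	3.5	c.928A>G	p.Ile310Val	HET	NR	.	NR	likely_benign	1/113284	.	.	.
FERMT2	AD#028	3.5	c.1077G>C	p.Gly359=	HET	NR	.	NR	likely_benign	1083/127414	.	.	.
FERMT2	AD#058	0	c.1538C>T	p.Thr513Met	HET	NR	.	NR	likely_pathogenic	487/129124	.	.	.
FERMT2	AD#060	0	c.1538C>T	p.Thr513Met	HET	NR	.	NR	likely_pathogenic	487/129124	.	.	.
INPP5D	AD#090	0	c.470G>A	p.Arg157Gln	HET	NR	.	NR	likely_pathogenic	300/127840	.	.	.
INPP5D	AD#089	3.5	c.2085C>T	p.Pro695=	HET	NR	.	NR	likely_benign	107/128314	.	.	.
MARK2	AD#090	0	c.1611C>T	p.Ser537=	HET	NR	.	NR	likely_benign	5/108824	.	.	.
MARK4	AD#060	0	c.1553C>T	p.Pro518Leu	HET	NR	.	NR	likely_benign	196/129058	.	.	.
PICALM	AD#014	0	c.1231G>C	p.Ala411Pro	HET	NR	.	NR	likely_pathogenic	321/128802	.	.	.
PLCG2	AD#032	3.5	c.3379C>A	p.Pro1127Thr	HET	NR	.	NR	likely_pathogenic	3/128682	.	.	.
PLCG2	AD#083	0	c.408G>A	p.Ala136=	HET	NR	.	NR	likely_benign	1/128708	.	.	.
PTK2B	AD#010	3.5	c.2591C>T	p.Ala864Val	HET	NR	.	Parkinson disease?	.	275/129154	.	.	.
RIN3	AD#022	0	c.2377T>C	p.Tyr793His	HET	NR	.	NR	likely_pathogenic	896/129136	.	.	.
TOMM40	AD#082	0	c.384C>G	p.Asn128Lys	HET	NR	.	NR	likely_benign	4/113466	.	.	.
ZCWPW1	AD#052	3.5	c.1834C>T	p.Leu612=	HET	NR	.	NR	likely_benign	1126/128540	.	.	.
ZCWPW1	AD#097	0	c.314A>G	p.Glu105Gly	HET	NR	.	NR	likely_pathogenic	623/128268	.	.	.
ZCWPW1	AD#088	0	c.283-5T>G	.	HET	NR	.	NR	likely_benign	1072/128080	.	.	.
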