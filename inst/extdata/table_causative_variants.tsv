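gene	patient_id	fh_score	hgvs_c	hgvs_p	zygosity	clinvar_class	conflicting_detail	hgmd_phenotype	prediction	gnomad_nfe	app_exon	literature_flags	reported_significance
APP	AD#089	3.5	c.1305C>T	p.Phe435=	HET	Benign	.	NR	.	132/128888	10	.	Benign
APP	AD#101	3.5	c.2137G>A	p.Ala713Thr	HET	Conflicting	likely_pathogenic:1;uncertain:2	Alzheimer disease	.	4/129100	17	.	Diagnostic
APP	AD#010	3.5	c.2229C>T	p.Thr743=	HET	NR	.	NR	likely_benign	NR	18	.	Benign
PSEN1	AD#043	0	c.104G>A	p.Arg35Gln	HET	Conflicting	uncertain:3;benign:1;likely_benign:1	Alzheimer disease?	.	37/129122	.	.	Risk factor
PSEN1	AD#102	3.5	c.253C>T	p.Leu85Phe	HET	NR	.	NR	likely_pathogenic	NR	.	.	Diagnostic
PSEN1	AD#055	1.5	c.275G>C	p.Cys92Ser	HET	Pathogenic	.	Alzheimer disease	.	NR	.	.	Diagnostic
PSEN1	AD#001	3.5	c.497T>A	p.Leu166His	HET	NR	.	Alzheimer disease, early-onset	.	NR	.	.	Diagnostic
PSEN1	AD#057	3.5	c.617G>C	p.Gly206Ala	HET	Pathogenic	.	Alzheimer disease	.	NR	.	.	Diagnostic
PSEN1	AD#012	1	c.791C>T	p.Pro264Leu	HET	Pathogenic	.	Alzheimer disease	.	NR	.	.	Diagnostic
PSEN1	AD#002	3.5	c.1172T>C	p.Val391Ala	HET	NR	.	Alzheimer disease	.	NR	.	.	Diagnostic
PSEN1	AD#101	3.5	c.1315A>G	p.Ile439Val	HET	NR	.	Alzheimer disease	.	NR	.	.	Diagnostic
PSEN1	AD#022	0	c.185G>A	p.Arg62His	HET	Benign	.	Alzheimer disease?	.	300/128852	.	.	Benign
PSEN2	AD#097	0	c.211C>T	p.Arg71Trp	HET	Benign	.	Alzheimer disease?	.	506/129030	.	prior_risk_report	Risk factor
PSEN2	AD#098	0	c.211C>T	p.Arg71Trp	HET	Benign	.	Alzheimer disease?	.	506/129030	.	prior_risk_report	Risk factor
PSEN2	AD#077	0	c.211C>T	p.Arg71Trp	HET	Benign	.	Alzheimer disease?	.	506/129030	.	prior_risk_report	Risk factor
PSEN2	AD#035	3	c.520A>G	p.Met174Val	HET	Benign	.	Alzheimer disease?	.	44/129182	.	prior_risk_report	Contributor of disease
PSEN2	AD#091	3.5	c.520A>G	p.Met174Val	HET	Benign	.	Alzheimer disease?	.	44/129182	.	prior_risk_report	Contributor of disease
PSEN2	AD#043	0	c.668G>C	p.Gly223Ala	HET	NR	.	Alzheimer disease	.	NR	.	.	Diagnostic
PSEN2	AD#065	3.5	c.708T>C	p.Ser236=	HET	Benign	.	NR	.	791/129088	.	.	Likely benign
PSEN2	AD#053	0	c.1186C>T	p.Leu396Phe	HET	NR	.	Alzheimer disease	.	1/113608	.	.	Diagnostic
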