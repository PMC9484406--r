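gene	patient_id	fh_score	hgvs_c	hgvs_p	zygosity	clinvar_class	conflicting_detail	hgmd_phenotype	prediction	gnomad_nfe	app_exon	literature_flags	reported_significance
ABCA7	AD#009	0	c.2126_2132delAGCAGGG	p.Glu709AlafsTer86	HET	Conflicting	uncertain:1;likely_benign:1	NR	.	250/104264	.	prior_risk_report;PTV	Risk factor
ABCA7	AD#052	3.5	c.2476G>A	p.Gly826Arg	HET	NR	.	NR	likely_pathogenic	95/126126	.	.	Risk factor
ABCA7	AD#088	0	c.2629G>A	p.Ala877Thr	HET	NR	.	NR	likely_benign	1014/127604	.	.	Likely benign
ABCA7	AD#006	0	c.3412A>C	p.Ser1138Arg	HET	NR	.	NR	likely_pathogenic	1/76428	.	.	Risk factor
ABCA7	AD#009	0	c.3472+5G>C	.	HET	NR	.	NR	likely_benign	2/112726	.	prior_risk_report	Risk factor
ABCA7	AD#083	0	c.4343G>A	p.Gly1448Asp	HET	NR	.	NR	likely_benign	72/127544	.	.	Likely benign
ABCA7	AD#007	0	c.4795G>A	p.Val1599Met	HET	Likely_benign	.	autism?	.	554/129150	.	.	Likely benign
ABCA7	AD#028	3.5	c.5570+5G>C	.	HET	VUS	.	Alzheimer disease?	.	432/114436	.	prior_risk_report	Risk factor
ABCA7	AD#099	0	c.5570+5G>C	.	HET	VUS	.	Alzheimer disease?	.	432/114436	.	prior_risk_report	Risk factor
SORL1	AD#094	3.5	c.133G>T	p.Asp45Tyr	HET	NR	.	NR	likely_pathogenic	4/39936	.	.	Risk factor
SORL1	AD#052	3.5	c.1805C>T	p.Ser602Leu	HET	NR	.	Alzheimer disease?	.	NR	.	.	Risk factor
SORL1	AD#096	0	c.3346A>G	p.Ile1116Val	HET	Benign	.	Alzheimer disease, late-onset?	.	1065/129098	.	.	Likely benign
SORL1	AD#062	0	c.4077C>T	p.Cys1359=	HET	VUS	.	NR	.	33/129196	.	.	Risk factor
SORL1	AD#097	0	c.5448T>C	p.Tyr1816=	HET	Benign	.	NR	.	285/128866	.	.	Likely benign
SORL1	AD#088	0	c.6150A>G	p.Glu2050=	HET	NR	.	NR	likely_benign	1/113030	.	.	Likely benign
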