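gene	patient_id	fh_score	hgvs_c	hgvs_p	zygosity	clinvar_class	conflicting_detail	hgmd_phenotype	prediction	gnomad_nfe	app_exon	literature_flags	reported_significance
TREM2	AD#085	0	c.140G>A	p.Arg47His	HET	Likely_benign	.	Alzheimer disease, increased risk	.	315/127748	.	prior_risk_report	Risk factor
TREM2	AD#026	3	c.287C>A	p.Thr96Lys	HET	Benign	.	frontotemporal dementia, increased risk	.	130/129182	.	prior_risk_report	Risk factor
TREM2	AD#026	3	c.632T>C	p.Leu211Pro	HET	Benign	.	Alzheimer disease, increased risk	.	144/129164	.	prior_risk_report	Risk factor
TREM2	AD#045	0	c.407G>A	p.Arg136Gln	HET	VUS	.	Alzheimer disease?	.	17/128820	.	.	Risk factor
TREM2	AD#089	3.5	c.668C>T	p.Thr223Ile	HET	Benign	.	Alzheimer disease?	.	49/129176	.	prior_risk_report	Risk factor
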