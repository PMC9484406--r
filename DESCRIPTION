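Package: eoadtriage
Title: Rare-Variant Triage and Clinical Classification for Early-Onset
    Alzheimer's Disease Gene-Panel Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for interpreting rare variants from
    gene-panel sequencing of early-onset Alzheimer's disease (EOAD) cohorts.
    Reads variant calls from VCF, applies depth / allelic-balance / minor
    allele frequency selection filters, annotates variants against dementia
    gene panels, ClinVar/HGMD classes and gnomAD non-Finnish European allele
    counts, classifies never-reported variants by in-silico predictor
    consensus voting, tests cohort-versus-reference allele-count enrichment
    with a two-sided Fisher exact test and Benjamini-Hochberg false discovery
    rate control, and maps every variant through a clinical decision tree
    (diagnostic, contributor of disease, risk factor, weak risk factor,
    benign). Cohort-level tools cover modified Goldman family-history
    scoring, CSF biomarker eligibility, APOE epsilon-allele determination
    from rs429358/rs7412 genotypes, and aggregation of genetically explained
    cases by familial and sporadic strata. A deterministic synthetic-cohort
    generator plants variants of every clinical category, filter decoys and
    APOE genotypes so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
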