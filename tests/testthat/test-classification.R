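test_that("the decision tree reproduces the canonical single-variant calls", {
  # known pathogenic in a causative gene -> diagnostic
  res <- classify_variant("PSEN1", "AD_CAUSATIVE", "Pathogenic",
                          hgmd_phenotype = "Alzheimer disease")
  expect_equal(res$category, "DIAGNOSTIC")
  expect_true(length(res$rationale) > 0)

  # conflicting interpretations with a pathogenic vote plus HGMD disease
  # support in a causative gene -> diagnostic
  res <- classify_variant("APP", "AD_CAUSATIVE", "Conflicting",
                          conflicting_detail = "likely_pathogenic:1;uncertain:2",
                          hgmd_phenotype = "Alzheimer disease")
  expect_equal(res$category, "DIAGNOSTIC")

  # novel causative-gene variant with likely-pathogenic consensus
  res <- classify_variant("PSEN1", "AD_CAUSATIVE", "NR", novel = TRUE,
                          consensus_label = "LIKELY_PATHOGENIC")
  expect_equal(res$category, "DIAGNOSTIC")

  # benign-tier with a prior risk report, sporadic carriers -> risk factor
  res <- classify_variant("PSEN2", "AD_CAUSATIVE", "Benign",
                          hgmd_phenotype = "Alzheimer disease?",
                          literature_flags = "prior_risk_report",
                          carriers_fh = rep("SPORADIC", 3), adj_p = 0.09)
  expect_equal(res$category, "RISK_FACTOR")

  # same knowledge, familial carrier and FDR-significant enrichment ->
  # contributor of disease
  res <- classify_variant("PSEN2", "AD_CAUSATIVE", "Benign",
                          hgmd_phenotype = "Alzheimer disease?",
                          literature_flags = "prior_risk_report",
                          carriers_fh = c("MODERATE", "SPORADIC"),
                          adj_p = 0.014)
  expect_equal(res$category, "CONTRIBUTOR")
  # both conditions are required conjunctively
  res <- classify_variant("PSEN2", "AD_CAUSATIVE", "Benign",
                          hgmd_phenotype = "Alzheimer disease?",
                          literature_flags = "prior_risk_report",
                          carriers_fh = "SPORADIC", adj_p = 0.014)
  expect_equal(res$category, "RISK_FACTOR")

  # VUS in an AD-risk gene -> risk factor
  res <- classify_variant("TREM2", "AD_RISK", "VUS",
                          hgmd_phenotype = "Alzheimer disease?",
                          carriers_fh = "SPORADIC", adj_p = 0.14)
  expect_equal(res$category, "RISK_FACTOR")

  # benign variant without a literature flag stays benign
  res <- classify_variant("PSEN1", "AD_CAUSATIVE", "Benign",
                          hgmd_phenotype = "Alzheimer disease?")
  expect_equal(res$category, "BENIGN")

  # VUS in an other-dementia gene -> weak risk
  res <- classify_variant("MAPT", "OTHER_DEMENTIA", "VUS",
                          hgmd_phenotype = "Alzheimer disease?")
  expect_equal(res$category, "WEAK_RISK")

  # novel likely-benign consensus -> likely benign
  res <- classify_variant("ABCA7", "AD_RISK", "NR", novel = TRUE,
                          consensus_label = "LIKELY_BENIGN")
  expect_equal(res$category, "LIKELY_BENIGN")

  # missing consensus for a novel variant is an error, not a guess
  expect_error(classify_variant("PSEN1", "AD_CAUSATIVE", "NR", novel = TRUE),
               "consensus")
})

test_that("every printed clinical-significance label is reproduced", {
  res <- packaged_pipeline()
  v <- res$variants[!is.na(res$variants$reported_significance), ]
  expect_gt(nrow(v), 30)
  # benign and likely-benign collapse into one tier: the printed tables use
  # the two labels interchangeably for identically-annotated variants
  tier <- function(x) ifelse(x %in% c("BENIGN", "LIKELY_BENIGN"), "BENIGN_TIER", x)
  printed <- c("Diagnostic" = "DIAGNOSTIC", "Risk factor" = "RISK_FACTOR",
               "Contributor of disease" = "CONTRIBUTOR",
               "Benign" = "BENIGN_TIER", "Likely benign" = "BENIGN_TIER")
  expect_equal(tier(v$category), unname(printed[v$reported_significance]))
})

test_that("classification is order-independent and patients count once", {
  res <- packaged_pipeline()
  v <- res$variants
  perm <- sample(nrow(v))
  v2 <- classify_table(v[perm, ], res$carriers)
  expect_equal(v2$category, v$category[perm])

  # AD#101 carries two diagnostic variants (APP + PSEN1) but counts once
  diag <- count_category_patients(v, res$carriers, "DIAGNOSTIC",
                                  genes = CAUSATIVE_GENES, n_cohort = 102)
  expect_equal(sum(res$carriers$patient_id == "AD#101"), 2)
  expect_true("AD#101" %in% diag$patients)
  expect_equal(diag$n, length(unique(diag$patients)))
})

test_that("patient explanation follows the four-source union rule", {
  res <- explain_patient("e3/e3", "DIAGNOSTIC", "PSEN1", "AD_CAUSATIVE")
  expect_equal(res$explained_by, "CAUSATIVE")
  res <- explain_patient("e4/e4")
  expect_equal(res$explained_by, "APOE44")
  res <- explain_patient("e3/e4", "BENIGN", "PSEN1", "AD_CAUSATIVE")
  expect_false(res$explained)
  res <- explain_patient("e3/e3", "RISK_FACTOR", "TREM2", "AD_RISK")
  expect_equal(res$explained_by, "MODERATE_RISK")
  res <- explain_patient("e3/e3", "WEAK_RISK", "MAPT", "OTHER_DEMENTIA")
  expect_equal(res$explained_by, "NON_AD_GENE")
  res <- explain_patient("e3/e3", "WEAK_RISK", "MAPT", "OTHER_DEMENTIA",
                         include_weak_risk = FALSE)
  expect_false(res$explained)
  # contributor alleles in causative genes count as causative
  res <- explain_patient("e4/e4", "CONTRIBUTOR", "PSEN2", "AD_CAUSATIVE")
  expect_setequal(res$explained_by, c("CAUSATIVE", "APOE44"))
})

test_that("cohort percentages recompute from counts with half-up rounding", {
  expect_equal(percent_of(46, 102), 45.10)
  expect_equal(percent_of(10, 46), 21.74)
  expect_equal(percent_of(9, 102), 8.82)
  expect_equal(round_half_up(0.125, 2), 0.13)  # half rounds up, not to even

  expl <- data.frame(patient_id = sprintf("P%d", 1:10),
                     familial = rep(c(TRUE, FALSE), 5),
                     explained = c(TRUE, TRUE, FALSE, FALSE, TRUE,
                                   FALSE, FALSE, FALSE, TRUE, TRUE),
                     causative = FALSE, apoe44 = FALSE,
                     moderate_risk = FALSE, non_ad_gene = FALSE)
  s <- summarize_cohort(expl)
  expect_equal(s$n_familial + s$n_sporadic, s$n_patients)
  expect_equal(s$explained_fraction_familial, percent_of(3, 5))
  expect_equal(s$explained_fraction_sporadic, percent_of(2, 5))
  empty <- summarize_cohort(expl[0, ])
  expect_equal(empty$n_patients, 0)
  expect_true(is.na(empty$explained_fraction_familial))
})
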