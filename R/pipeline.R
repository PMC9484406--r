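#' @title End-to-end triage pipelines
#' @name pipeline
#' @description
#' Two entry points tie the modules together. [run_triage()] is the VCF
#' route: read calls, apply the selection filters, annotate against
#' knowledge tables keyed by genomic coordinates, consensus-classify novel
#' variants, test enrichment, run the clinical decision tree and aggregate
#' per-patient explanation status. [run_fixture_pipeline()] is the
#' fixture-table route operating directly on curated per-table variant
#' transcriptions keyed by (gene, HGVS-c).
NULL

#' Run the full triage pipeline on a cohort bundle
#'
#' @param bundle A `cohort_bundle` (from [generate_cohort()] or
#'   [read_bundle()]).
#' @param config A [filter_config()].
#' @param alpha Contributor significance threshold.
#' @param include_weak_risk Passed to the patient-explanation rule.
#' @return List with `kept`, `rejected` (filtered calls), `variants`
#'   (annotated, enriched and classified, one row per distinct kept
#'   variant), `carriers`, `explanations` and `summary`.
#' @export
run_triage <- function(bundle, config = filter_config(), alpha = 0.05,
                       include_weak_risk = TRUE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  patients <- bundle$patients
  if (is.null(patients$familial)) {
    gs <- patients$goldman_score
    if (!all(gs %in% GOLDMAN_SCORES | is.na(gs)))
      gs <- parse_goldman_score(gs)
    patients$goldman_score <- gs
    patients$fh_strength <- goldman_strength(gs)
    patients$familial <- !is.na(gs) & gs != "NONE"
  }
  if (is.null(patients$apoe_genotype) &&
      all(c("rs429358_gt", "rs7412_gt") %in% names(patients))) {
    apoe <- apoe_from_snps(patients$rs429358_gt, patients$rs7412_gt)
    patients$apoe_genotype <- apoe$genotype
  }

  knowledge <- fill_knowledge_columns(bundle$knowledge)
  kb <- collapse_knowledge(knowledge, max_ref_af = Inf)

  # join reference frequencies onto calls by genomic key for the MAF filter
  calls <- bundle$calls
  vkey <- variant_key(kb$variants)
  idx <- match(variant_key(calls), vkey)
  calls$ref_af <- kb$variants$ref_af[idx]

  filtered <- apply_filters(calls, config, bundle$regions)
  kept <- filtered$kept

  # restrict the variant table to kept variants; carriers from kept calls
  kept_keys <- unique(variant_key(kept))
  variants <- kb$variants[vkey %in% kept_keys, , drop = FALSE]
  fh <- patients$fh_strength[match(kept$patient_id, patients$patient_id)]
  carriers <- data.frame(table = "all", gene = kept$gene,
                         hgvs_c = kb$variants$hgvs_c[match(variant_key(kept), vkey)],
                         patient_id = kept$patient_id,
                         fh_strength = fh, zygosity = kept$zygosity,
                         stringsAsFactors = FALSE)

  variants <- annotate_variants(variants)
  variants <- consensus_for_variants(variants, bundle$verdicts)
  variants <- enrich_table(variants, carriers, nrow(patients),
                           family = "all")
  variants <- classify_table(variants, carriers, alpha = alpha)

  explanations <- explain_patients(patients, variants, carriers,
                                   include_weak_risk = include_weak_risk)
  list(kept = kept, rejected = filtered$rejected, variants = variants,
       carriers = carriers, patients = patients,
       explanations = explanations,
       summary = summarize_cohort(explanations))
}

#' Run the fixture-table pipeline on curated variant tables
#'
#' Loads per-table variant transcriptions (knowledge + carriers keyed by
#' gene and HGVS-c), annotates them against the gene panels, derives
#' in-silico consensus labels for novel variants from the verdict table,
#' tests enrichment per source table (the BH family), and classifies every
#' variant.
#'
#' @param knowledge_paths Character vector of knowledge TSV paths.
#' @param verdict_path Path to the predictor-verdict TSV.
#' @param metadata_path Path to the patient metadata TSV.
#' @param table_names Optional family labels per knowledge table.
#' @param n_cohort Cohort size for allele denominators and percentages
#'   (default: patients in the metadata table).
#' @param alpha Contributor significance threshold.
#' @param panels Gene panels (default [default_gene_panels()]).
#' @return List with `variants` (classified), `carriers`, `patients`,
#'   `explanations` and `summary`.
#' @export
run_fixture_pipeline <- function(knowledge_paths, verdict_path,
                                 metadata_path, table_names = NULL,
                                 n_cohort = NULL, alpha = 0.05,
                                 panels = default_gene_panels()) {
  kb <- load_knowledge_tables(knowledge_paths, table_names)
  patients <- read_patient_metadata(metadata_path)
  if (is.null(n_cohort)) n_cohort <- nrow(patients)
  verdicts <- read_verdicts(verdict_path)

  variants <- annotate_variants(kb$variants, panels)
  variants <- consensus_for_variants(variants, verdicts)
  variants <- enrich_table(variants, kb$carriers, n_cohort)
  variants <- classify_table(variants, kb$carriers, alpha = alpha)

  explanations <- explain_patients(patients, variants, kb$carriers)
  list(variants = variants, carriers = kb$carriers, patients = patients,
       explanations = explanations, summary = summarize_cohort(explanations),
       n_cohort = n_cohort)
}

#' Run the fixture pipeline on the packaged cohort-study tables
#'
#' Convenience wrapper over [run_fixture_pipeline()] using the packaged
#' transcriptions of the study's results tables (causative genes, TREM2,
#' other-dementia genes, ABCA7/SORL1 risk genes, GWAS genes), the synthetic
#' verdict table and the synthetic 102-patient metadata completion.
#'
#' @param alpha Contributor significance threshold.
#' @return See [run_fixture_pipeline()].
#' @export
run_packaged_fixtures <- function(alpha = 0.05) {
  tables <- c(causative = "table_causative_variants.tsv",
              trem2 = "table_trem2_variants.tsv",
              other_dementia = "table_other_dementia_variants.tsv",
              ad_risk = "table_ad_risk_variants.tsv",
              gwas = "table_gwas_variants.tsv")
  run_fixture_pipeline(
    knowledge_paths = vapply(tables, eoad_fixture_path, character(1)),
    verdict_path = eoad_fixture_path("predictor_verdicts_synthetic.tsv"),
    metadata_path = eoad_fixture_path("cohort_metadata_synthetic.tsv"),
    table_names = names(tables), alpha = alpha)
}
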