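#' @title Clinical classification decision tree
#' @name clinical-classification
#' @description
#' Maps every annotated variant to one clinical category. Rule order (first
#' match wins):
#' \enumerate{
#'   \item In an AD-causative gene (APP/PSEN1/PSEN2): ClinVar pathogenic or
#'     likely pathogenic, a definite HGMD disease annotation, or conflicting
#'     ClinVar interpretations that contain pathogenic votes together with a
#'     definite HGMD disease annotation -> \strong{diagnostic}.
#'   \item Never-reported variant in an AD-causative gene with a
#'     likely-pathogenic in-silico consensus -> \strong{diagnostic}.
#'   \item In an AD-causative or AD-risk gene (TREM2/ABCA7/SORL1), a
#'     risk-candidate (ClinVar VUS; conflicting interpretations without a
#'     pathogenic majority; ClinVar-unreported with a questionable
#'     dementia-related HGMD annotation; benign-tier or novel likely-benign
#'     variant carrying a prior-risk literature flag) ->
#'     \strong{contributor of disease} when at least one carrier is familial
#'     AND the BH-adjusted enrichment p-value is below `alpha`, otherwise
#'     \strong{risk factor}. Never-reported AD-risk-gene variants with
#'     likely-pathogenic consensus -> \strong{risk factor}.
#'   \item In an other-dementia gene: pathogenic / likely pathogenic / VUS
#'     (known, via conflicting interpretations containing pathogenic votes,
#'     via a definite HGMD annotation, or by likely-pathogenic consensus) ->
#'     \strong{weak risk}.
#'   \item Known benign / likely benign, or novel consensus likely benign ->
#'     \strong{benign} / \strong{likely benign}.
#'   \item Otherwise \strong{unclassified}.
#' }
NULL

CLINICAL_CATEGORIES <- c("DIAGNOSTIC", "CONTRIBUTOR", "RISK_FACTOR",
                         "WEAK_RISK", "LIKELY_BENIGN", "BENIGN",
                         "UNCLASSIFIED")

# internal: vote bookkeeping for conflicting ClinVar interpretations
conflict_votes <- function(detail) {
  votes <- parse_conflicting_detail(detail)[[1]]
  if (is.null(votes)) abort("Conflicting class requires conflicting_detail")
  path <- sum(votes[names(votes) %in% c("pathogenic", "likely_pathogenic")])
  benign <- sum(votes[names(votes) %in% c("benign", "likely_benign")])
  list(pathogenic = path, benign = benign, uncertain = sum(votes) - path - benign,
       total = sum(votes))
}

#' Classify one variant through the clinical decision tree
#'
#' @param gene Gene symbol.
#' @param panel Panel name (`AD_CAUSATIVE`, `AD_RISK`, `OTHER_DEMENTIA`,
#'   `AD_GWAS` or `NONE`).
#' @param clinvar_class ClinVar class label (see package vocabulary).
#' @param conflicting_detail Vote multiset string when `clinvar_class` is
#'   `"Conflicting"`.
#' @param hgmd_phenotype HGMD phenotype string or `"NR"`; a trailing `"?"`
#'   or an "increased risk" annotation marks a non-definite entry.
#' @param novel Logical; not reported in ClinVar nor HGMD.
#' @param consensus_label In-silico consensus label for novel variants
#'   (`NA` otherwise).
#' @param literature_flags Semicolon-separated flags
#'   (`prior_risk_report` promotes benign-tier variants to risk candidates).
#' @param carriers_fh Character vector of carrier family-history strengths
#'   (`STRONG` / `MODERATE` / `SPORADIC`), one per carrier.
#' @param adj_p BH-adjusted enrichment p-value (`NA` when not testable).
#' @param alpha Significance threshold for the contributor rule
#'   (default 0.05).
#' @return List with `category` and `rationale` (ordered rule identifiers).
#' @export
classify_variant <- function(gene, panel, clinvar_class,
                             conflicting_detail = NA, hgmd_phenotype = "NR",
                             novel = FALSE, consensus_label = NA,
                             literature_flags = NA,
                             carriers_fh = character(), adj_p = NA,
                             alpha = 0.05) {
  if (!clinvar_class %in% CLINVAR_CLASSES)
    abort("unknown clinvar_class '%s'", clinvar_class)
  if (novel && is.na(consensus_label))
    abort("novel variant %s requires a consensus label", gene)
  rationale <- character(0)

  definite_hgmd <- hgmd_definite(hgmd_phenotype)
  known_path <- clinvar_class %in% c("Pathogenic", "Likely_pathogenic")
  conflict <- if (clinvar_class == "Conflicting")
    conflict_votes(conflicting_detail) else NULL

  # rule 1: pathogenic tier in a causative gene -> diagnostic
  if (panel == "AD_CAUSATIVE") {
    if (known_path) {
      return(list(category = "DIAGNOSTIC",
                  rationale = c("causative_gene", "clinvar_pathogenic")))
    }
    if (definite_hgmd && !clinvar_class %in% c("Benign", "Likely_benign")) {
      return(list(category = "DIAGNOSTIC",
                  rationale = c("causative_gene", "hgmd_disease_causing")))
    }
    if (!is.null(conflict) && conflict$pathogenic > 0 &&
        hgmd_dementia_related(hgmd_phenotype)) {
      return(list(category = "DIAGNOSTIC",
                  rationale = c("causative_gene",
                                "conflicting_with_pathogenic_votes",
                                "hgmd_disease_support")))
    }
    # rule 2: novel + likely-pathogenic consensus -> diagnostic
    if (novel && identical(consensus_label, "LIKELY_PATHOGENIC")) {
      return(list(category = "DIAGNOSTIC",
                  rationale = c("causative_gene", "novel_consensus_lp")))
    }
  }

  # rule 3: risk candidates in causative / AD-risk genes
  if (panel %in% c("AD_CAUSATIVE", "AD_RISK")) {
    if (panel == "AD_RISK" && novel &&
        identical(consensus_label, "LIKELY_PATHOGENIC")) {
      return(list(category = "RISK_FACTOR",
                  rationale = c("ad_risk_gene", "novel_consensus_lp")))
    }
    candidate <- FALSE
    if (clinvar_class == "VUS") {
      candidate <- TRUE; rationale <- c(rationale, "clinvar_vus")
    } else if (!is.null(conflict) && conflict$pathogenic <= conflict$total / 2) {
      candidate <- TRUE; rationale <- c(rationale, "conflicting_uncertain")
    } else if (clinvar_class == "NR" && !novel &&
               hgmd_dementia_related(hgmd_phenotype) && !definite_hgmd) {
      candidate <- TRUE; rationale <- c(rationale, "hgmd_questionable_dementia")
    } else if ((clinvar_class %in% c("Benign", "Likely_benign") ||
                (novel && identical(consensus_label, "LIKELY_BENIGN"))) &&
               has_flag(literature_flags, "prior_risk_report")) {
      candidate <- TRUE; rationale <- c(rationale, "prior_risk_report")
    }
    if (candidate) {
      familial <- any(carriers_fh %in% c("STRONG", "MODERATE"))
      enriched <- !is.na(adj_p) && adj_p < alpha
      if (familial && enriched) {
        return(list(category = "CONTRIBUTOR",
                    rationale = c(rationale, "familial_carrier",
                                  "enriched_vs_reference")))
      }
      return(list(category = "RISK_FACTOR", rationale = rationale))
    }
  }

  # rule 4: other-dementia genes -> weak risk
  if (panel == "OTHER_DEMENTIA") {
    weak <- known_path ||
      clinvar_class == "VUS" ||
      (!is.null(conflict) && conflict$pathogenic > 0) ||
      (definite_hgmd && hgmd_dementia_related(hgmd_phenotype)) ||
      (novel && identical(consensus_label, "LIKELY_PATHOGENIC"))
    if (weak) {
      return(list(category = "WEAK_RISK",
                  rationale = c("other_dementia_gene", "pathogenic_or_vus")))
    }
  }

  # rule 5: benign tier
  if (clinvar_class == "Benign")
    return(list(category = "BENIGN", rationale = "clinvar_benign"))
  if (clinvar_class == "Likely_benign")
    return(list(category = "LIKELY_BENIGN", rationale = "clinvar_likely_benign"))
  if (novel && identical(consensus_label, "LIKELY_BENIGN"))
    return(list(category = "LIKELY_BENIGN", rationale = "novel_consensus_lb"))
  if (!is.null(conflict) && conflict$pathogenic <= conflict$total / 2)
    return(list(category = "LIKELY_BENIGN", rationale = "conflicting_mostly_benign"))

  list(category = "UNCLASSIFIED", rationale = character(0))
}

#' Classify every variant in an annotated, enriched table
#'
#' Convenience wrapper running [classify_variant()] over the rows of a
#' variant-level data frame (as produced by [load_knowledge_tables()],
#' [annotate_variants()], [consensus_for_variants()] and [enrich_table()]).
#' Carrier family-history strengths come from the carriers table (column
#' `fh_score`, numeric dialect) or from patient metadata.
#'
#' @param variants Variant-level data frame.
#' @param carriers Carrier-level data frame with `gene`, `hgvs_c`,
#'   `patient_id` and `fh_score` (or `fh_strength`).
#' @param alpha Contributor significance threshold (default 0.05).
#' @return `variants` with `category` and `rationale` columns added.
#' @export
classify_table <- function(variants, carriers, alpha = 0.05) {
  if (is.null(carriers$fh_strength)) {
    carriers$fh_strength <- goldman_strength(parse_goldman_score(carriers$fh_score))
  }
  ckey <- paste(carriers$gene, carriers$hgvs_c, sep = ":")
  variants$category <- NA_character_
  variants$rationale <- NA_character_
  for (i in seq_len(nrow(variants))) {
    k <- paste(variants$gene[i], variants$hgvs_c[i], sep = ":")
    res <- classify_variant(
      gene = variants$gene[i], panel = variants$panel[i],
      clinvar_class = variants$clinvar_class[i],
      conflicting_detail = variants$conflicting_detail[i],
      hgmd_phenotype = variants$hgmd_phenotype[i],
      novel = variants$novel[i],
      consensus_label = variants$consensus_label[i],
      literature_flags = variants$literature_flags[i],
      carriers_fh = carriers$fh_strength[ckey == k],
      adj_p = if (!is.null(variants$adj_p)) variants$adj_p[i] else NA,
      alpha = alpha)
    variants$category[i] <- res$category
    variants$rationale[i] <- paste(res$rationale, collapse = ">")
  }
  variants
}

#' Count distinct patients carrying variants of given categories
#'
#' A patient carrying several qualifying variants counts once.
#'
#' @param classified Classified variant-level data frame (with `category`).
#' @param carriers Carrier-level data frame.
#' @param categories Category values to select.
#' @param genes Optional gene restriction.
#' @param n_cohort Cohort size for the percentage (default: distinct
#'   patients in `carriers`).
#' @return Named list `n` (distinct patients) and `percent` (of `n_cohort`,
#'   two decimals, half-up).
#' @export
count_category_patients <- function(classified, carriers, categories,
                                    genes = NULL, n_cohort = NULL) {
  sel <- classified$category %in% categories
  if (!is.null(genes)) sel <- sel & classified$gene %in% genes
  vkey <- paste(classified$gene, classified$hgvs_c, sep = ":")[sel]
  ckey <- paste(carriers$gene, carriers$hgvs_c, sep = ":")
  patients <- unique(carriers$patient_id[ckey %in% vkey])
  if (is.null(n_cohort)) n_cohort <- length(unique(carriers$patient_id))
  list(n = length(patients), percent = percent_of(length(patients), n_cohort),
       patients = patients)
}

#' Explanation status of one patient
#'
#' A patient counts as genetically explained when at least one of four
#' sources applies: a causative allele (diagnostic or contributor variant in
#' an AD-causative gene), APOE e4/e4 homozygosity, a moderate-risk allele
#' (risk-factor variant in APP, PSEN1, PSEN2 or TREM2), or a weak-risk
#' variant in a gene causative for another dementia.
#'
#' @param apoe_genotype The patient's APOE genotype (e.g. `"e3/e4"`, `NA`
#'   allowed).
#' @param variant_categories Character vector of clinical categories of the
#'   variants this patient carries.
#' @param variant_genes Gene symbols parallel to `variant_categories`.
#' @param variant_panels Panel names parallel to `variant_categories`.
#' @param moderate_risk_genes Genes whose risk-factor alleles count as
#'   moderate risk (default APP, PSEN1, PSEN2, TREM2).
#' @param include_weak_risk Count weak-risk variants as explaining
#'   (default `TRUE`).
#' @return List with `explained_by` (subset of `CAUSATIVE`, `APOE44`,
#'   `MODERATE_RISK`, `NON_AD_GENE`) and `explained` (logical).
#' @export
explain_patient <- function(apoe_genotype, variant_categories = character(),
                            variant_genes = character(),
                            variant_panels = character(),
                            moderate_risk_genes = c("APP", "PSEN1", "PSEN2",
                                                    "TREM2"),
                            include_weak_risk = TRUE) {
  by <- character(0)
  if (any(variant_categories %in% c("DIAGNOSTIC", "CONTRIBUTOR") &
          variant_panels == "AD_CAUSATIVE"))
    by <- c(by, "CAUSATIVE")
  if (!is.na(apoe_genotype) && apoe_normalise(apoe_genotype) == "e4/e4")
    by <- c(by, "APOE44")
  if (any(variant_categories == "RISK_FACTOR" &
          variant_genes %in% moderate_risk_genes))
    by <- c(by, "MODERATE_RISK")
  if (include_weak_risk && any(variant_categories == "WEAK_RISK"))
    by <- c(by, "NON_AD_GENE")
  list(explained_by = by, explained = length(by) > 0)
}

#' Explanation status for every patient in a cohort
#'
#' @param patients Patient metadata data frame (with `patient_id`,
#'   `apoe_genotype`, `familial`).
#' @param classified Classified variant-level data frame.
#' @param carriers Carrier-level data frame.
#' @param ... Passed to [explain_patient()].
#' @return Data frame with one row per patient: `patient_id`, `familial`,
#'   `explained`, `explained_by` (`;`-joined), and one logical column per
#'   source.
#' @export
explain_patients <- function(patients, classified, carriers, ...) {
  ckey <- paste(carriers$gene, carriers$hgvs_c, sep = ":")
  vkey <- paste(classified$gene, classified$hgvs_c, sep = ":")
  out <- data.frame(patient_id = patients$patient_id,
                    familial = patients$familial,
                    explained = FALSE, explained_by = "",
                    causative = FALSE, apoe44 = FALSE,
                    moderate_risk = FALSE, non_ad_gene = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(patients))) {
    mine <- ckey[carriers$patient_id == patients$patient_id[i]]
    idx <- match(unique(mine), vkey)
    idx <- idx[!is.na(idx)]
    res <- explain_patient(patients$apoe_genotype[i],
                           classified$category[idx],
                           classified$gene[idx],
                           classified$panel[idx], ...)
    out$explained[i] <- res$explained
    out$explained_by[i] <- paste(res$explained_by, collapse = ";")
    out$causative[i] <- "CAUSATIVE" %in% res$explained_by
    out$apoe44[i] <- "APOE44" %in% res$explained_by
    out$moderate_risk[i] <- "MODERATE_RISK" %in% res$explained_by
    out$non_ad_gene[i] <- "NON_AD_GENE" %in% res$explained_by
  }
  out
}

#' Cohort-level summary of explained cases
#'
#' @param explanations Data frame from [explain_patients()].
#' @return Named list with cohort counts, familial/sporadic strata, and the
#'   explained fractions per stratum (percentages, two decimals, half-up).
#' @export
summarize_cohort <- function(explanations) {
  n <- nrow(explanations)
  fam <- explanations$familial
  n_fam <- sum(fam)
  n_spo <- sum(!fam)
  list(
    n_patients = n,
    n_familial = n_fam,
    n_sporadic = n_spo,
    percent_familial = percent_of(n_fam, n),
    percent_sporadic = percent_of(n_spo, n),
    explained_familial = sum(explanations$explained & fam),
    explained_sporadic = sum(explanations$explained & !fam),
    explained_fraction_familial = percent_of(sum(explanations$explained & fam), n_fam),
    explained_fraction_sporadic = percent_of(sum(explanations$explained & !fam), n_spo),
    by_source = list(
      causative = sum(explanations$causative),
      apoe44 = sum(explanations$apoe44),
      moderate_risk = sum(explanations$moderate_risk),
      non_ad_gene = sum(explanations$non_ad_gene)))
}
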