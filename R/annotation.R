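#' @title Variant annotation against packaged knowledge tables
#' @name annotation
#' @description
#' Joins filtered variants to gene panels, ClinVar/HGMD classes, reference
#' population allele counts and literature flags. Knowledge tables are keyed
#' by (`gene`, `hgvs_c`); in VCF mode a coordinate-to-HGVS mapping (extra
#' `chrom`/`pos`/`ref`/`alt` columns in the knowledge table) acts as the
#' adapter.
NULL

CLINVAR_CLASSES <- c("Pathogenic", "Likely_pathogenic", "VUS", "Conflicting",
                     "Likely_benign", "Benign", "NR")

#' Parse a reference allele-count string
#'
#' Allele counts are printed `"alt/total"` (e.g. `"506/129030"`); `"NR"`
#' (not reported) parses to missing counts.
#'
#' @param x Character vector of count strings.
#' @return Data frame with integer columns `ac_alt`, `ac_total` and numeric
#'   `af` (`NA` throughout for not-reported).
#' @examples
#' parse_allele_count(c("506/129030", "NR"))
#' @export
parse_allele_count <- function(x) {
  out <- data.frame(ac_alt = rep(NA_integer_, length(x)),
                    ac_total = rep(NA_integer_, length(x)),
                    af = rep(NA_real_, length(x)))
  live <- !is.na(x) & toupper(trimws(x)) != "NR"
  if (any(live)) {
    parts <- strsplit(trimws(x[live]), "/", fixed = TRUE)
    bad <- vapply(parts, function(p)
      length(p) != 2 || anyNA(suppressWarnings(as.integer(p))), logical(1))
    if (any(bad))
      abort("malformed allele-count string(s): %s",
            paste(unique(x[live][bad]), collapse = ", "))
    alt <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    tot <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    if (any(alt < 0 | alt > tot))
      abort("allele counts must satisfy 0 <= alt <= total")
    out$ac_alt[live] <- alt
    out$ac_total[live] <- tot
    out$af[live] <- ifelse(tot > 0, alt / tot, NA_real_)
  }
  out
}

#' Parse a ClinVar "conflicting interpretations" vote multiset
#'
#' Encoded `"class:count;class:count"`, e.g.
#' `"likely_pathogenic:1;uncertain:2"`.
#'
#' @param x Character vector (`NA` allowed).
#' @return List of named integer vectors (votes per class), `NULL` elements
#'   for missing input.
#' @export
parse_conflicting_detail <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    counts <- vapply(parts, function(p) as.integer(p[2]), integer(1))
    names(counts) <- vapply(parts, function(p) tolower(trimws(p[1])), character(1))
    ok <- names(counts) %in% c("pathogenic", "likely_pathogenic", "uncertain",
                               "likely_benign", "benign")
    if (!all(ok) || anyNA(counts))
      abort("malformed conflicting_detail: '%s'", s)
    counts
  })
}

#' Default dementia gene panels
#'
#' Four non-overlapping panels: `AD_CAUSATIVE` (APP, PSEN1, PSEN2),
#' `AD_RISK` (TREM2, ABCA7, SORL1), `OTHER_DEMENTIA` (twelve genes causative
#' for the ALS/FTD spectrum and related dementias) and `AD_GWAS`
#' (34 GWAS susceptibility genes; the packaged list is user-overridable via
#' [read_gene_panels()]).
#'
#' @return Named list of character vectors of gene symbols.
#' @export
default_gene_panels <- function() {
  read_gene_panels(eoad_fixture_path("gene_panels.yaml"))
}

#' Read gene panel definitions from YAML
#'
#' The YAML maps panel names to gene lists. Panels must be pairwise
#' disjoint; a gene in two panels is a configuration error rejected at load.
#'
#' @param path Path to a YAML file.
#' @return Named list of character vectors.
#' @export
read_gene_panels <- function(path) {
  cfg <- yaml::read_yaml(path)
  panels <- lapply(cfg, function(p) {
    genes <- if (is.list(p) && !is.null(p$genes)) p$genes else p
    as.character(unlist(genes))
  })
  all_genes <- unlist(panels)
  dup <- unique(all_genes[duplicated(all_genes)])
  if (length(dup) > 0)
    abort("gene(s) assigned to more than one panel: %s", paste(dup, collapse = ", "))
  panels
}

#' Load one or more knowledge tables
#'
#' Each TSV carries one row per (`gene`, `hgvs_c`, `patient_id`) with the
#' columns `gene`, `patient_id`, `fh_score`, `hgvs_c`, `hgvs_p`, `zygosity`,
#' `clinvar_class`, `conflicting_detail`, `hgmd_phenotype`, `prediction`,
#' `gnomad_nfe`, `app_exon`, `literature_flags` (and optionally
#' `reported_significance` plus `chrom`/`pos`/`ref`/`alt` mapping columns).
#' Rows for the same variant are collapsed into a variant-level record with
#' its carrier list; the same (`gene`, `hgvs_c`) appearing with contradictory
#' knowledge fields is rejected.
#'
#' @param paths Character vector of TSV paths.
#' @param table_names Optional labels recorded per input table (defaults to
#'   file base names); used as the enrichment-test family below.
#' @param max_ref_af Sanity ceiling on the reference allele frequency of any
#'   row (default 0.01: curated rare-variant tables must only contain rare
#'   variants, so a violation flags a transcription error). Set to `Inf`
#'   for tables that legitimately carry common variants, e.g. synthetic
#'   bundles with planted frequency decoys.
#' @export
load_knowledge_tables <- function(paths, table_names = NULL,
                                  max_ref_af = 0.01) {
  if (is.null(table_names))
    table_names <- tools::file_path_sans_ext(basename(paths))
  required <- c("gene", "patient_id", "hgvs_c", "clinvar_class",
                "hgmd_phenotype", "gnomad_nfe")
  tabs <- mapply(function(p, nm) {
    df <- read_tsv_strict(p, required)
    df$table <- nm
    df
  }, paths, table_names, SIMPLIFY = FALSE)
  carriers <- do.call(rbind, lapply(tabs, fill_knowledge_columns))
  rownames(carriers) <- NULL
  collapse_knowledge(carriers, max_ref_af)
}

# internal: ensure all optional knowledge columns exist
fill_knowledge_columns <- function(df) {
  for (col in c("hgvs_p", "zygosity", "conflicting_detail", "prediction",
                "app_exon", "literature_flags", "fh_score",
                "reported_significance"))
    if (is.null(df[[col]])) df[[col]] <- NA
  if (is.null(df$table)) df$table <- "all"
  df
}

# internal: collapse carrier-level knowledge rows to variant level
collapse_knowledge <- function(carriers, max_ref_af = 0.01) {
  carriers$clinvar_class[is.na(carriers$clinvar_class)] <- "NR"
  carriers$hgmd_phenotype[is.na(carriers$hgmd_phenotype)] <- "NR"
  carriers$zygosity[is.na(carriers$zygosity)] <- "HET"
  bad <- setdiff(unique(carriers$clinvar_class), CLINVAR_CLASSES)
  if (length(bad) > 0)
    abort("unknown clinvar_class label(s): %s", paste(bad, collapse = ", "))

  key <- paste(carriers$gene, carriers$hgvs_c, sep = ":")
  knowledge_cols <- c("gene", "hgvs_c", "hgvs_p", "clinvar_class",
                      "conflicting_detail", "hgmd_phenotype", "prediction",
                      "gnomad_nfe", "app_exon", "literature_flags", "table",
                      "reported_significance", "chrom", "pos", "ref", "alt")
  knowledge_cols <- intersect(knowledge_cols, names(carriers))
  first <- !duplicated(key)
  variants <- carriers[first, knowledge_cols, drop = FALSE]
  rownames(variants) <- NULL
  # contradictory duplicate keys are data errors; repeated identical
  # knowledge (additional carriers) is expected
  for (k in unique(key[duplicated(key)])) {
    rows <- carriers[key == k, knowledge_cols, drop = FALSE]
    if (nrow(unique(rows)) != 1)
      abort("conflicting knowledge rows for duplicate key %s", k)
  }
  counts <- parse_allele_count(variants$gnomad_nfe)
  variants$ref_ac_alt <- counts$ac_alt
  variants$ref_ac_total <- counts$ac_total
  variants$ref_af <- counts$af
  if (any(variants$ref_af >= max_ref_af, na.rm = TRUE))
    abort("knowledge table contains non-rare variant(s) (reference AF >= %g): %s",
          max_ref_af,
          paste(variants$hgvs_c[which(variants$ref_af >= max_ref_af)], collapse = ", "))
  variants$effect_class <- infer_effect_class(variants$hgvs_c, variants$hgvs_p)
  variants$novel <- variants$clinvar_class == "NR" & variants$hgmd_phenotype == "NR"
  list(variants = variants,
       carriers = carriers[, c("table", "gene", "hgvs_c", "patient_id",
                               "fh_score", "zygosity")])
}

#' Infer a coarse molecular effect class from HGVS notation
#'
#' `SILENT` for synonymous protein changes (`p.X123=`), `SPLICE_REGION` for
#' intronic/flanking changes (no protein change, offset notation in the
#' cDNA), `PTV` for frameshift/stop-gain, `INDEL_INFRAME` for in-frame
#' deletions/duplications, `MISSENSE` otherwise.
#'
#' @param hgvs_c,hgvs_p Character vectors of cDNA and protein HGVS strings
#'   (`hgvs_p` may be `NA` for intronic variants).
#' @return Character vector of effect classes.
#' @export
infer_effect_class <- function(hgvs_c, hgvs_p) {
  n <- length(hgvs_c)
  out <- rep("MISSENSE", n)
  p_missing <- is.na(hgvs_p) | !nzchar(hgvs_p)
  out[p_missing & grepl("[0-9][+-][0-9]", hgvs_c)] <- "SPLICE_REGION"
  out[p_missing & !grepl("[0-9][+-][0-9]", hgvs_c)] <- "OTHER"
  silent <- !p_missing & grepl("=$", hgvs_p)
  out[silent] <- "SILENT"
  ptv <- !p_missing & grepl("fs|Ter", hgvs_p)
  out[ptv] <- "PTV"
  inframe <- !p_missing & !ptv & grepl("del|dup|ins", hgvs_p)
  out[inframe] <- "INDEL_INFRAME"
  out
}

#' Annotate variants with panel membership
#'
#' A pure join: each variant receives the unique panel containing its gene
#' (`NONE` when no panel does) and its novelty flag (not reported in either
#' ClinVar or HGMD). Reference population counts are carried through
#' unchanged; a variant absent from the reference stays `NA` here (rarity
#' imputation to zero happens only inside the filter).
#'
#' @param variants Data frame of variant-level knowledge (from
#'   [load_knowledge_tables()]`$variants`).
#' @param panels Named list of gene panels (default [default_gene_panels()]).
#' @return The input with a `panel` column added.
#' @export
annotate_variants <- function(variants, panels = default_gene_panels()) {
  all_genes <- unlist(panels)
  if (any(duplicated(all_genes)))
    abort("panels overlap; fix the panel configuration")
  panel_of <- rep(names(panels), lengths(panels))
  names(panel_of) <- all_genes
  variants$panel <- unname(panel_of[variants$gene])
  variants$panel[is.na(variants$panel)] <- "NONE"
  variants
}

#' Count distinct variants, genes and carrier patients within a panel
#'
#' @param variants Annotated variant-level data frame (with `panel`).
#' @param carriers Carrier-level data frame (from [load_knowledge_tables()]).
#' @param panel Panel name, or `NULL` for all panels.
#' @param genes Optional explicit gene set overriding `panel`.
#' @return Named list `n_variants`, `n_genes`, `n_patients`.
#' @export
count_variants_and_genes <- function(variants, carriers = NULL, panel = NULL,
                                     genes = NULL) {
  sel <- rep(TRUE, nrow(variants))
  if (!is.null(panel)) sel <- sel & variants$panel == panel
  if (!is.null(genes)) sel <- sel & variants$gene %in% genes
  v <- variants[sel, , drop = FALSE]
  n_patients <- NA_integer_
  if (!is.null(carriers)) {
    ckey <- paste(carriers$gene, carriers$hgvs_c, sep = ":")
    vkey <- paste(v$gene, v$hgvs_c, sep = ":")
    n_patients <- length(unique(carriers$patient_id[ckey %in% vkey]))
  }
  list(n_variants = nrow(v), n_genes = length(unique(v$gene)),
       n_patients = n_patients)
}

# internal: is an HGMD phenotype annotation a definite disease entry?
# Trailing "?" marks a questionable entry and "increased risk" a
# risk-association entry; neither counts as a definite disease-causing
# annotation.
hgmd_definite <- function(phenotype) {
  reported <- !is.na(phenotype) & phenotype != "NR"
  reported & !grepl("\\?\\s*$", phenotype) &
    !grepl("increased risk", phenotype, ignore.case = TRUE)
}

# internal: does an HGMD annotation refer to a dementia/neurodegeneration
# phenotype (relevant to the risk-factor rules)?
hgmd_dementia_related <- function(phenotype) {
  reported <- !is.na(phenotype) & phenotype != "NR"
  reported & grepl("alzheimer|dementia|neurodegener",
                   phenotype, ignore.case = TRUE)
}

# internal: does a literature_flags field carry a given flag?
has_flag <- function(flags, flag) {
  flags <- as.character(flags)
  !is.na(flags) & vapply(strsplit(flags, ";", fixed = TRUE),
                         function(f) flag %in% trimws(f), logical(1))
}
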