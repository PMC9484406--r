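#' @title In-silico consensus classification of never-reported variants
#' @name insilico-consensus
#' @description
#' Variants absent from ClinVar and HGMD are graded by consensus voting over
#' effect-class-specific predictor panels: missense (and protein-truncating /
#' in-frame indel) variants by PolyPhen-2, M-CAP, CADD and MutationTaster;
#' intronic splice-region variants by NetGene2, MaxEntScan and Human Splicing
#' Finder; silent variants by MutationTaster, CADD and FATHMM-XF. A missense
#' variant is likely pathogenic when at least three of the four tools call it
#' damaging; the three-tool classes use a simple majority (at least two of
#' three). Never-reported APP variants outside exons 16 and 17 (the
#' amyloid-beta-coding exons) are likely benign regardless of votes.
NULL

#' Predictor tool panels per effect class
#' @export
CONSENSUS_TOOLS <- list(
  MISSENSE = c("POLYPHEN2", "MCAP", "CADD", "MUTATIONTASTER"),
  PTV = c("POLYPHEN2", "MCAP", "CADD", "MUTATIONTASTER"),
  INDEL_INFRAME = c("POLYPHEN2", "MCAP", "CADD", "MUTATIONTASTER"),
  SPLICE_REGION = c("NETGENE2", "MAXENTSCAN", "HSF"),
  SILENT = c("MUTATIONTASTER", "CADD", "FATHMM_XF"))

#' Consensus-classify a never-reported variant from predictor verdicts
#'
#' @param effect_class One of `names(CONSENSUS_TOOLS)`.
#' @param verdicts Named character vector `tool -> verdict`, verdicts over
#'   `{DAMAGING, TOLERATED, NO_CALL}`. The tool set must match the effect
#'   class; `NO_CALL` counts as not damaging.
#' @param gene Gene symbol (needed for the APP positional rule).
#' @param app_exon Exon number for APP variants; required when `gene` is
#'   `"APP"`.
#' @param missense_threshold Damaging votes needed for the four-tool classes
#'   (default 3).
#' @param majority_threshold Damaging votes needed for the three-tool classes
#'   (default 2).
#' @return List with `label` (`"LIKELY_PATHOGENIC"` or `"LIKELY_BENIGN"`),
#'   `votes_damaging`, `votes_total` and `rule_applied`.
#' @examples
#' consensus_classify("MISSENSE", c(POLYPHEN2 = "DAMAGING", MCAP = "DAMAGING",
#'                                  CADD = "DAMAGING", MUTATIONTASTER = "TOLERATED"),
#'                    gene = "PSEN1")
#' @export
consensus_classify <- function(effect_class, verdicts, gene = NULL,
                               app_exon = NULL, missense_threshold = 3,
                               majority_threshold = 2) {
  if (!effect_class %in% names(CONSENSUS_TOOLS))
    abort("no predictor panel for effect class '%s'", effect_class)
  expected <- CONSENSUS_TOOLS[[effect_class]]
  got <- names(verdicts)
  if (is.null(got) || !setequal(got, expected))
    abort("verdict tool set {%s} does not match the %s panel {%s}",
          paste(got, collapse = ", "), effect_class,
          paste(expected, collapse = ", "))
  if (!all(verdicts %in% c("DAMAGING", "TOLERATED", "NO_CALL")))
    abort("verdicts must be DAMAGING, TOLERATED or NO_CALL")

  if (!is.null(gene) && !is.na(gene) && gene == "APP") {
    if (is.null(app_exon) || is.na(app_exon))
      abort("APP variant requires app_exon for the positional rule")
    if (!app_exon %in% c(16, 17)) {
      return(list(label = "LIKELY_BENIGN",
                  votes_damaging = sum(verdicts == "DAMAGING"),
                  votes_total = length(expected),
                  rule_applied = "app_outside_exon_16_17"))
    }
  }
  threshold <- if (length(expected) == 4) missense_threshold else majority_threshold
  damaging <- sum(verdicts == "DAMAGING")
  label <- if (damaging >= threshold) "LIKELY_PATHOGENIC" else "LIKELY_BENIGN"
  list(label = label, votes_damaging = damaging,
       votes_total = length(expected),
       rule_applied = sprintf("%d_of_%d_damaging", threshold, length(expected)))
}

#' Read a predictor verdict table
#'
#' TSV with columns `gene`, `hgvs_c`, `tool`, `verdict`; one row per tool
#' per variant, strict vocabulary.
#'
#' @param path Path to the TSV.
#' @return Data frame of verdicts.
#' @export
read_verdicts <- function(path) {
  df <- read_tsv_strict(path, c("gene", "hgvs_c", "tool", "verdict"))
  tools_known <- unique(unlist(CONSENSUS_TOOLS))
  bad <- setdiff(unique(df$tool), tools_known)
  if (length(bad) > 0)
    abort("unknown predictor tool(s): %s", paste(bad, collapse = ", "))
  if (!all(df$verdict %in% c("DAMAGING", "TOLERATED", "NO_CALL")))
    abort("verdicts must be DAMAGING, TOLERATED or NO_CALL")
  if (anyDuplicated(df[c("gene", "hgvs_c", "tool")]))
    abort("duplicate (gene, hgvs_c, tool) verdict rows")
  df
}

#' Consensus-classify every novel variant in an annotated table
#'
#' @param variants Annotated variant-level data frame (with `novel`,
#'   `effect_class`, `app_exon`).
#' @param verdicts Verdict data frame from [read_verdicts()].
#' @param ... Passed to [consensus_classify()].
#' @return `variants` with columns `consensus_label`, `votes_damaging`,
#'   `votes_total`, `consensus_rule` added (`NA` for non-novel variants).
#' @export
consensus_for_variants <- function(variants, verdicts, ...) {
  variants$consensus_label <- NA_character_
  variants$votes_damaging <- NA_integer_
  variants$votes_total <- NA_integer_
  variants$consensus_rule <- NA_character_
  idx <- which(variants$novel)
  vkey <- paste(verdicts$gene, verdicts$hgvs_c, sep = ":")
  for (i in idx) {
    k <- paste(variants$gene[i], variants$hgvs_c[i], sep = ":")
    rows <- verdicts[vkey == k, , drop = FALSE]
    if (nrow(rows) == 0)
      abort("novel variant %s has no predictor verdicts", k)
    v <- rows$verdict
    names(v) <- rows$tool
    res <- consensus_classify(variants$effect_class[i], v,
                              gene = variants$gene[i],
                              app_exon = variants$app_exon[i], ...)
    variants$consensus_label[i] <- res$label
    variants$votes_damaging[i] <- res$votes_damaging
    variants$votes_total[i] <- res$votes_total
    variants$consensus_rule[i] <- res$rule_applied
  }
  variants
}

#' Count distinct novel variants with a given consensus label
#'
#' @param variants Variant-level data frame with `consensus_label`.
#' @param label `"LIKELY_PATHOGENIC"` or `"LIKELY_BENIGN"`.
#' @param genes Optional gene restriction.
#' @return Integer count.
#' @export
count_consensus_label <- function(variants, label, genes = NULL) {
  sel <- !is.na(variants$consensus_label) & variants$consensus_label == label
  if (!is.null(genes)) sel <- sel & variants$gene %in% genes
  sum(sel)
}
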