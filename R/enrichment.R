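#' @title Cohort-versus-reference allele-count enrichment
#' @name enrichment-stats
#' @description
#' Per-variant 2x2 allele-count tables (cohort alternate/total vs reference
#' population alternate/total) tested with a two-sided Fisher exact test and
#' adjusted across a test family with the Benjamini-Hochberg step-up
#' procedure. The two-sided p-value follows the point-probability
#' ("minimum-likelihood") convention: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table, with a 1e-7
#' relative tolerance on the comparison. Variants absent from the reference
#' are not testable and are excluded from the family.
NULL

#' Two-sided Fisher exact test on a 2x2 allele-count table
#'
#' @param a,b Cohort alternate and non-alternate allele counts.
#' @param c,d Reference alternate and non-alternate allele counts.
#' @return Two-sided p-value in `[0, 1]`. A table with a zero margin carries
#'   no information and returns 1 by convention.
#' @examples
#' fisher_exact_two_sided(2, 202, 44, 129138)
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || anyNA(c(a, b, c, d)))
    abort("allele-count table entries must be non-negative integers")
  m <- a + b          # cohort alleles
  n <- c + d          # reference alleles
  k <- a + c          # alternate alleles
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: order p-values ascending, set `q_(i) = min_{j >= i}
#' p_(j) * m / j` clipped at 1, and return the adjusted values in input
#' order (stable under ties).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order; `adjusted >= raw`
#'   elementwise.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    abort("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Build the cohort side of an allele-count table from carrier genotypes
#'
#' Heterozygous and hemizygous carriers contribute one alternate allele,
#' homozygous carriers two. The cohort allele denominator is
#' `2 * n_genotyped` minus one per hemizygous patient.
#'
#' @param zygosities Character vector over `{HET, HOM_ALT, HEMI}`, one per
#'   carrier.
#' @param n_genotyped Number of genotyped patients in the cohort.
#' @param ref_ac_alt,ref_ac_total Reference population allele counts (`NA`
#'   when the variant is not reported there).
#' @return Named list `cohort_alt`, `cohort_total`, `ref_alt`, `ref_total`,
#'   `testable`.
#' @export
enrich_variant <- function(zygosities, n_genotyped, ref_ac_alt, ref_ac_total) {
  if (!all(zygosities %in% c("HET", "HOM_ALT", "HEMI")))
    abort("zygosities must be HET, HOM_ALT or HEMI")
  if (length(zygosities) > n_genotyped)
    abort("more carriers than genotyped patients")
  cohort_alt <- sum(ifelse(zygosities == "HOM_ALT", 2L, 1L))
  cohort_total <- 2L * n_genotyped - sum(zygosities == "HEMI")
  testable <- !is.na(ref_ac_alt) && !is.na(ref_ac_total) && ref_ac_total > 0
  list(cohort_alt = cohort_alt, cohort_total = cohort_total,
       ref_alt = if (testable) ref_ac_alt else NA_integer_,
       ref_total = if (testable) ref_ac_total else NA_integer_,
       testable = testable)
}

#' Enrichment testing across a variant table
#'
#' Builds the per-variant allele tables, runs the two-sided Fisher exact
#' test on every testable variant, and BH-adjusts within families given by
#' the `family` column (one family per results table by default, mirroring
#' per-table adjusted p-value reporting). Untestable variants (absent from
#' the reference) get `NA` p-values and do not count toward family size.
#'
#' @param variants Variant-level data frame with `gene`, `hgvs_c`,
#'   `ref_ac_alt`, `ref_ac_total` and a `table` column (the family).
#' @param carriers Carrier-level data frame with `gene`, `hgvs_c`,
#'   `zygosity`.
#' @param n_genotyped Number of genotyped patients.
#' @param family Optional family labels overriding `variants$table`; a
#'   single label pools everything into one family.
#' @return `variants` with columns `cohort_alt`, `cohort_total`, `ref_alt`,
#'   `ref_total`, `testable`, `raw_p`, `adj_p`, `family_size` added.
#' @export
enrich_table <- function(variants, carriers, n_genotyped, family = NULL) {
  if (is.null(family)) {
    family <- if (!is.null(variants$table)) variants$table
    else rep("all", nrow(variants))
  }
  family <- rep_len(family, nrow(variants))
  ckey <- paste(carriers$gene, carriers$hgvs_c, sep = ":")
  variants$cohort_alt <- NA_integer_
  variants$cohort_total <- NA_integer_
  variants$ref_alt <- NA_integer_
  variants$ref_total <- NA_integer_
  variants$testable <- FALSE
  variants$raw_p <- NA_real_
  for (i in seq_len(nrow(variants))) {
    k <- paste(variants$gene[i], variants$hgvs_c[i], sep = ":")
    zyg <- carriers$zygosity[ckey == k]
    if (length(zyg) == 0) next
    at <- enrich_variant(zyg, n_genotyped,
                         variants$ref_ac_alt[i], variants$ref_ac_total[i])
    variants$cohort_alt[i] <- at$cohort_alt
    variants$cohort_total[i] <- at$cohort_total
    variants$ref_alt[i] <- at$ref_alt
    variants$ref_total[i] <- at$ref_total
    variants$testable[i] <- at$testable
    if (at$testable)
      variants$raw_p[i] <- fisher_exact_two_sided(
        at$cohort_alt, at$cohort_total - at$cohort_alt,
        at$ref_alt, at$ref_total - at$ref_alt)
  }
  variants$adj_p <- NA_real_
  variants$family_size <- NA_integer_
  for (fam in unique(family)) {
    idx <- which(family == fam & variants$testable)
    if (length(idx) == 0) next
    variants$adj_p[idx] <- bh_adjust(variants$raw_p[idx])
    variants$family_size[idx] <- length(idx)
  }
  variants
}
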