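#' @title Cohort model: family history, CSF eligibility and APOE genotypes
#' @name cohort-model
#' @description
#' Patient-level domain rules for an early-onset Alzheimer's disease (EOAD)
#' cohort: the modified Goldman family-history score and its
#' strong/moderate/sporadic strata, the CSF biomarker profile used as an
#' AD-pathophysiology eligibility gate, and APOE epsilon-allele determination
#' from the rs429358/rs7412 coding SNPs.
NULL

#' Valid modified Goldman score labels
#'
#' `S1`: at least three affected in two generations with EOAD, one a
#' first-degree relative of the other two; `S1_5`: as S1 but late-onset AD;
#' `S2`: at least three relatives with AD without full autosomal-dominant
#' inheritance; `S3`: a single affected first- or second-degree relative with
#' EOAD; `S3_5`: as S3 but late-onset; `NONE`: no family history (sporadic).
#' @export
GOLDMAN_SCORES <- c("S1", "S1_5", "S2", "S3", "S3_5", "NONE")

#' Map a modified Goldman score to family-history strength
#'
#' Strong family history corresponds to scores S1 and S1.5
#' (autosomal-dominant-like aggregation), moderate to S2/S3/S3.5, and
#' patients without family history are sporadic.
#'
#' @param score Character vector of Goldman score labels (see
#'   [GOLDMAN_SCORES]).
#' @return Character vector over `{"STRONG", "MODERATE", "SPORADIC"}`.
#' @examples
#' goldman_strength(c("S1", "S3_5", "NONE"))
#' @export
goldman_strength <- function(score) {
  bad <- setdiff(unique(score[!is.na(score)]), GOLDMAN_SCORES)
  if (length(bad) > 0)
    abort("unknown Goldman score label(s): %s", paste(bad, collapse = ", "))
  out <- rep(NA_character_, length(score))
  out[score %in% c("S1", "S1_5")] <- "STRONG"
  out[score %in% c("S2", "S3", "S3_5")] <- "MODERATE"
  out[score == "NONE"] <- "SPORADIC"
  out
}

#' Parse numeric-style Goldman scores ("0", "1", "1.5", "2", "3", "3.5")
#'
#' Cohort tables often print the score as a number, with 0 meaning no family
#' history. This helper converts that dialect to the canonical labels.
#'
#' @param x Character or numeric vector of printed scores.
#' @return Character vector of [GOLDMAN_SCORES] labels.
#' @export
parse_goldman_score <- function(x) {
  map <- c("0" = "NONE", "1" = "S1", "1.5" = "S1_5",
           "2" = "S2", "3" = "S3", "3.5" = "S3_5")
  key <- sub("\\.0$", "", trimws(format(as.numeric(x), trim = TRUE)))
  key[is.na(x)] <- NA
  out <- unname(map[key])
  bad <- unique(key[!is.na(key) & is.na(out)])
  if (length(bad) > 0)
    abort("unknown Goldman score value(s): %s", paste(bad, collapse = ", "))
  out
}

#' CSF Alzheimer's disease biomarker profile
#'
#' Eligibility rule for a characteristic AD CSF profile: phosphorylated-tau /
#' A-beta-42 ratio strictly above `ptau_cutoff` AND A-beta-42 / A-beta-40
#' ratio strictly below `ab_cutoff`. Both inequalities are strict, so a
#' ratio sitting exactly on a cutoff does not qualify.
#'
#' @param ptau_ab42_ratio Numeric, p-tau/Abeta42 ratio (dimensionless, > 0).
#' @param ab42_ab40_ratio Numeric, Abeta42/Abeta40 ratio (dimensionless, > 0).
#' @param ptau_cutoff Lower cutoff for the p-tau/Abeta42 ratio (default 0.108).
#' @param ab_cutoff Upper cutoff for the Abeta42/Abeta40 ratio (default 0.68).
#' @return Logical vector: `TRUE` (AD profile), `FALSE`, or `NA` when either
#'   ratio is missing (indeterminate, distinct from `FALSE`).
#' @examples
#' csf_ad_profile(0.20, 0.50)   # TRUE
#' csf_ad_profile(0.108, 0.50)  # FALSE: boundary fails the strict ">"
#' @export
csf_ad_profile <- function(ptau_ab42_ratio, ab42_ab40_ratio,
                           ptau_cutoff = 0.108, ab_cutoff = 0.68) {
  if (any(ptau_ab42_ratio <= 0, na.rm = TRUE) ||
      any(ab42_ab40_ratio <= 0, na.rm = TRUE))
    abort("CSF ratios must be positive")
  ptau_ab42_ratio > ptau_cutoff & ab42_ab40_ratio < ab_cutoff
}

#' APOE epsilon genotype from rs429358 and rs7412 genotypes
#'
#' The APOE epsilon alleles are haplotypes of two coding SNPs:
#' rs429358-T with rs7412-C gives epsilon-3, T/T gives epsilon-2, C/C gives
#' epsilon-4 and C/T gives the rare epsilon-1. Unphased double heterozygotes
#' (C/T at both sites) are compatible with either e2/e4 or e1/e3; the
#' population-frequency convention resolves them as e2/e4 and the result is
#' flagged ambiguous.
#'
#' @param rs429358_gt,rs7412_gt Character vectors of unordered genotypes over
#'   `{C, T}`, written `"T/T"`, `"C/T"`, etc.
#' @return A data frame with columns `allele1`, `allele2` (sorted epsilon
#'   labels, e.g. `"e3"`), `genotype` (e.g. `"e3/e4"`), and `ambiguous`
#'   (logical). Missing input genotypes yield `NA` rows.
#' @examples
#' apoe_from_snps("T/T", "C/C")  # e3/e3
#' apoe_from_snps("C/C", "C/C")  # e4/e4
#' apoe_from_snps("C/T", "C/T")  # e2/e4, flagged ambiguous
#' @export
apoe_from_snps <- function(rs429358_gt, rs7412_gt) {
  n <- max(length(rs429358_gt), length(rs7412_gt))
  rs429358_gt <- rep_len(rs429358_gt, n)
  rs7412_gt <- rep_len(rs7412_gt, n)

  parse_gt <- function(gt, rsid) {
    alleles <- strsplit(toupper(gsub("\\s", "", gt)), "/", fixed = TRUE)
    lapply(seq_along(alleles), function(i) {
      a <- alleles[[i]]
      if (length(a) == 1 && is.na(gt[i])) return(c(NA, NA))
      if (length(a) != 2 || !all(a %in% c("C", "T")))
        abort("%s genotype '%s' is not an unordered pair over {C, T}", rsid, gt[i])
      sort(a)
    })
  }
  g1 <- parse_gt(rs429358_gt, "rs429358")
  g2 <- parse_gt(rs7412_gt, "rs7412")

  # haplotype table: (rs429358, rs7412) -> epsilon allele
  hap <- function(a429358, a7412) {
    if (a429358 == "T" && a7412 == "C") return("e3")
    if (a429358 == "T" && a7412 == "T") return("e2")
    if (a429358 == "C" && a7412 == "C") return("e4")
    "e1"  # C/T
  }

  out <- data.frame(allele1 = character(n), allele2 = character(n),
                    genotype = character(n), ambiguous = logical(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- g1[[i]]; b <- g2[[i]]
    if (anyNA(a) || anyNA(b)) {
      out[i, c("allele1", "allele2", "genotype")] <- NA_character_
      out$ambiguous[i] <- NA
      next
    }
    het1 <- a[1] != a[2]; het2 <- b[1] != b[2]
    if (het1 && het2) {
      # phase-ambiguous: {e2/e4, e1/e3}; resolved e2/e4 by frequency convention
      eps <- c("e2", "e4"); ambiguous <- TRUE
    } else {
      # at most one site heterozygous: the two haplotypes are determined
      eps <- sort(c(hap(a[1], b[1]), hap(a[2], b[2])))
      ambiguous <- FALSE
    }
    out$allele1[i] <- eps[1]; out$allele2[i] <- eps[2]
    out$genotype[i] <- paste(eps, collapse = "/")
    out$ambiguous[i] <- ambiguous
  }
  out
}

#' Normalise an APOE genotype string to an unordered pair
#'
#' @param genotype Character vector like `"e4/e3"` (order-insensitive,
#'   `"ε"`-prefixed forms accepted).
#' @return Character vector of canonical unordered genotypes (`"e3/e4"`).
#' @export
apoe_normalise <- function(genotype) {
  out <- rep(NA_character_, length(genotype))
  ok <- !is.na(genotype)
  parts <- strsplit(gsub("ε", "e", tolower(gsub("\\s", "", genotype[ok]))),
                    "/", fixed = TRUE)
  bad <- vapply(parts, function(p)
    length(p) != 2 || !all(p %in% c("e1", "e2", "e3", "e4")), logical(1))
  if (any(bad))
    abort("invalid APOE genotype(s): %s",
          paste(unique(genotype[ok][bad]), collapse = ", "))
  out[ok] <- vapply(parts, function(p) paste(sort(p), collapse = "/"), character(1))
  out
}

#' Count APOE epsilon-4 genotype categories in a cohort
#'
#' @param genotypes Character vector of APOE genotypes (any order, `NA` for
#'   unresolved).
#' @return Named list with counts `e4_homozygous` (e4/e4), `e4_heterozygous`
#'   (exactly one e4 allele), `other` (no e4 allele) and `unknown` (missing
#'   genotype). The four buckets partition the input.
#' @examples
#' count_apoe_categories(c("e4/e4", "e3/e4", "e2/e4", "e3/e3"))
#' @export
count_apoe_categories <- function(genotypes) {
  g <- apoe_normalise(genotypes)
  n_e4 <- ifelse(is.na(g), NA_integer_,
                 vapply(strsplit(g, "/", fixed = TRUE),
                        function(p) sum(p == "e4"), integer(1)))
  list(e4_homozygous = sum(n_e4 == 2, na.rm = TRUE),
       e4_heterozygous = sum(n_e4 == 1, na.rm = TRUE),
       other = sum(n_e4 == 0, na.rm = TRUE),
       unknown = sum(is.na(g)))
}

#' Read a patient metadata table
#'
#' Expected columns: `patient_id`, `sex` (`M`/`F`), `age_at_onset`,
#' `goldman_score` (either canonical labels or the numeric dialect), and
#' either `apoe_genotype` or the SNP genotypes `rs429358_gt`/`rs7412_gt`
#' (from which the epsilon genotype is derived). Optional CSF ratio columns
#' `ptau_ab42_ratio`, `ab42_ab40_ratio`. Missing values are `"."`.
#'
#' @param path Path to a UTF-8 TSV file with a header.
#' @param max_onset Upper bound (exclusive) on age at onset for an EOAD
#'   cohort; onsets at or above it are rejected. Default 65.
#' @return Data frame with one row per patient, canonical `goldman_score`,
#'   derived `fh_strength`, `familial` (logical), `apoe_genotype` and
#'   `apoe_ambiguous` columns.
#' @export
read_patient_metadata <- function(path, max_onset = 65) {
  df <- read_tsv_strict(path, c("patient_id", "sex", "age_at_onset",
                                "goldman_score"))
  if (anyDuplicated(df$patient_id))
    abort("duplicate patient_id(s): %s",
          paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  if (!all(df$sex %in% c("M", "F") | is.na(df$sex)))
    abort("sex must be 'M' or 'F'")
  if (any(df$age_at_onset >= max_onset, na.rm = TRUE))
    abort("age_at_onset >= %d violates the early-onset bound", max_onset)

  gs <- df$goldman_score
  if (!all(gs %in% GOLDMAN_SCORES | is.na(gs)))
    gs <- parse_goldman_score(gs)
  df$goldman_score <- gs
  df$fh_strength <- goldman_strength(gs)
  df$familial <- !is.na(gs) & gs != "NONE"

  if ("apoe_genotype" %in% names(df)) {
    df$apoe_genotype <- apoe_normalise(df$apoe_genotype)
    df$apoe_ambiguous <- FALSE
  } else if (all(c("rs429358_gt", "rs7412_gt") %in% names(df))) {
    apoe <- apoe_from_snps(df$rs429358_gt, df$rs7412_gt)
    df$apoe_genotype <- apoe$genotype
    df$apoe_ambiguous <- apoe$ambiguous
  } else {
    df$apoe_genotype <- NA_character_
    df$apoe_ambiguous <- NA
  }
  df
}
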