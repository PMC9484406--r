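#' @title Variant selection filters
#' @name variant-filtering
#' @description
#' Selection criteria applied to panel-sequencing calls before
#' interpretation: (i) the variant lies in a target coding interval expanded
#' by a flanking margin, (ii) read depth at least `min_depth`, (iii) for
#' heterozygous calls an allelic balance inside `[ab_min, ab_max]`, and
#' (iv) minor allele frequency in the reference population below `max_maf`
#' (variants absent from the reference count as frequency 0 and pass).
NULL

#' Filter configuration
#'
#' @param min_depth Minimum read depth (default 10).
#' @param ab_min,ab_max Inclusive allelic-balance bounds for heterozygous
#'   calls (defaults 0.30 and 0.70). Homozygous and hemizygous calls are
#'   exempt from the balance filter.
#' @param max_maf Reference-population allele-frequency ceiling, exclusive
#'   (default 0.01).
#' @param flank_bp Flanking margin added to each side of every target
#'   interval (default 7 bases).
#' @param keep_missing_quality Keep calls whose depth/allele-depth fields are
#'   missing instead of rejecting them with reason `missing_quality`
#'   (default `FALSE`).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10, ab_min = 0.30, ab_max = 0.70,
                          max_maf = 0.01, flank_bp = 7,
                          keep_missing_quality = FALSE) {
  if (min_depth < 1) abort("min_depth must be >= 1")
  if (!(ab_min >= 0 && ab_min < ab_max && ab_max <= 1))
    abort("allelic-balance bounds must satisfy 0 <= ab_min < ab_max <= 1")
  if (!(max_maf > 0 && max_maf <= 1)) abort("max_maf must be in (0, 1]")
  if (flank_bp < 0) abort("flank_bp must be non-negative")
  structure(list(min_depth = min_depth, ab_min = ab_min, ab_max = ab_max,
                 max_maf = max_maf, flank_bp = flank_bp,
                 keep_missing_quality = keep_missing_quality),
            class = "filter_config")
}

#' Allelic balance of a call
#'
#' Fraction of reads supporting the alternate allele,
#' `alt_depth / (ref_depth + alt_depth)`. Missing depths propagate as `NA`,
#' as does a zero informative-read total.
#'
#' @param ref_depth,alt_depth Integer read counts.
#' @return Numeric vector of fractions in `[0, 1]` or `NA`.
#' @examples
#' allelic_balance(12, 8) # 0.4
#' @export
allelic_balance <- function(ref_depth, alt_depth) {
  total <- ref_depth + alt_depth
  ifelse(is.na(total) | total == 0, NA_real_, alt_depth / total)
}

#' Read a target-region table
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `gene`. Coordinates
#' are 0-based half-open (the BED convention); `#`-prefixed header lines are
#' ignored, and files written by [write_region_set()] state the convention in
#' such a line. Intervals are merged per gene.
#'
#' @param path Path to the TSV.
#' @return Data frame of class `region_set` with 0-based half-open intervals.
#' @export
read_region_set <- function(path) {
  df <- read_tsv_strict(path, c("chrom", "start", "end", "gene"))
  as_region_set(df)
}

#' Build a region set from a data frame
#' @param df Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `gene` columns.
#' @return The merged, validated `region_set`.
#' @export
as_region_set <- function(df) {
  if (any(df$start >= df$end)) abort("region intervals must have start < end")
  if (any(df$start < 0)) abort("region starts must be >= 0")
  # merge overlapping intervals per (chrom, gene)
  pieces <- split(df, paste(df$chrom, df$gene, sep = "\r"))
  merged <- do.call(rbind, lapply(pieces, function(p) {
    p <- p[order(p$start), , drop = FALSE]
    out <- p[1, , drop = FALSE]
    for (i in seq_len(nrow(p))[-1]) {
      last <- nrow(out)
      if (p$start[i] <= out$end[last]) {
        out$end[last] <- max(out$end[last], p$end[i])
      } else {
        out <- rbind(out, p[i, , drop = FALSE])
      }
    }
    out
  }))
  rownames(merged) <- NULL
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  structure(merged, class = c("region_set", "data.frame"))
}

#' Write a region set as a BED-like TSV
#' @param regions A `region_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_set <- function(regions, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open (BED convention)", con)
  utils::write.table(as.data.frame(regions), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# internal: TRUE where the 1-based position pos falls within a region
# (expanded by flank_bp) for matching chrom
in_regions <- function(chrom, pos, regions, flank_bp = 0) {
  if (is.null(regions)) return(rep(TRUE, length(pos)))
  hit <- rep(FALSE, length(pos))
  pos0 <- pos - 1L  # 1-based VCF position -> 0-based coordinate
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos0 >= regions$start[i] - flank_bp &
                    pos0 < regions$end[i] + flank_bp)
  }
  hit
}

#' Apply the selection filters to variant calls
#'
#' Each call is tested against the criteria in the fixed order
#' region -> depth -> allelic balance -> MAF; a rejected call carries the
#' first criterion it failed as its `reason` (one of `"region"`, `"depth"`,
#' `"allelic_balance"`, `"maf"`, or `"missing_quality"`). The kept and
#' rejected sets partition the input, and the operation is idempotent and
#' independent of row order.
#'
#' @param calls Data frame of variant calls with columns `chrom`, `pos`,
#'   `depth`, `ref_depth`, `alt_depth`, `zygosity`, and (for the MAF filter)
#'   either `ref_af` or `ref_ac_alt` + `ref_ac_total`. Reference frequencies
#'   absent (`NA`) are treated as 0 (never reported) and pass.
#' @param config A [filter_config()].
#' @param regions Optional `region_set`; `NULL` disables the region filter.
#' @return A list with data frames `kept` and `rejected`; `rejected` has an
#'   extra `reason` column.
#' @export
apply_filters <- function(calls, config = filter_config(), regions = NULL) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(calls)
  if (n == 0) {
    rejected <- calls
    rejected$reason <- character(0)
    return(list(kept = calls, rejected = rejected))
  }
  if (!is.null(calls$ref_af)) {
    ref_af <- calls$ref_af
  } else if (!is.null(calls$ref_ac_alt)) {
    ref_af <- ifelse(is.na(calls$ref_ac_alt) | is.na(calls$ref_ac_total) |
                       calls$ref_ac_total == 0,
                     NA_real_, calls$ref_ac_alt / calls$ref_ac_total)
  } else {
    ref_af <- rep(NA_real_, n)
  }
  ref_af[is.na(ref_af)] <- 0  # never reported in the reference: frequency 0

  reason <- rep(NA_character_, n)

  ok_region <- in_regions(calls$chrom, calls$pos, regions, config$flank_bp)
  reason[!ok_region] <- "region"

  miss_depth <- is.na(calls$depth)
  idx <- is.na(reason) & miss_depth & !config$keep_missing_quality
  reason[idx] <- "missing_quality"
  idx <- is.na(reason) & !miss_depth & calls$depth < config$min_depth
  reason[idx] <- "depth"

  is_het <- !is.na(calls$zygosity) & calls$zygosity == "HET"
  ab <- allelic_balance(calls$ref_depth, calls$alt_depth)
  idx <- is.na(reason) & is_het & is.na(ab) & !config$keep_missing_quality
  reason[idx] <- "missing_quality"
  idx <- is.na(reason) & is_het & !is.na(ab) &
    (ab < config$ab_min | ab > config$ab_max)
  reason[idx] <- "allelic_balance"

  idx <- is.na(reason) & ref_af >= config$max_maf
  reason[idx] <- "maf"

  kept <- calls[is.na(reason), , drop = FALSE]
  rejected <- calls[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Count distinct variants among calls
#'
#' Variants are identified by genomic key (`chrom`, `pos`, `ref`, `alt`)
#' when those columns are present, otherwise by (`gene`, `hgvs_c`). Multiple
#' carriers of the same variant count once.
#'
#' @param calls Data frame of calls.
#' @param genes Optional gene-symbol set to restrict the count.
#' @return Integer count of distinct variants.
#' @export
count_distinct_variants <- function(calls, genes = NULL) {
  if (nrow(calls) == 0) return(0L)
  if (!is.null(genes)) calls <- calls[calls$gene %in% genes, , drop = FALSE]
  if (nrow(calls) == 0) return(0L)
  key <- variant_key(calls)
  length(unique(key))
}

# internal: canonical variant identity for a calls/annotation data frame
variant_key <- function(df) {
  if (all(c("chrom", "pos", "ref", "alt") %in% names(df)) &&
      !all(is.na(df$pos))) {
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  } else {
    paste(df$gene, df$hgvs_c, sep = ":")
  }
}
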