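#' Read variant calls from a VCF file
#'
#' Parses a VCF v4.x file into one row per alternate allele per carrier
#' sample. Multi-allelic records are decomposed; genotypes that carry no
#' alternate allele (`0/0`, `./.`) are skipped. Depth uses the genotype-level
#' `FORMAT/DP` when present, falling back to the site-level `INFO/DP`;
#' per-allele depths come from `FORMAT/AD`. Missing quality fields stay
#' missing (`NA`), never zero. Indel alleles are trimmed (shared suffix then
#' shared prefix removed, position adjusted) so that keys match normalised
#' annotation tables.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param sample_map Optional named character vector renaming VCF sample
#'   columns to patient identifiers; every VCF sample must then be present in
#'   its names.
#' @return Data frame with columns `patient_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `gene` (from `INFO/GENE` when present), `depth`,
#'   `ref_depth`, `alt_depth`, `zygosity` (`HET`, `HOM_ALT`, `HEMI`).
#' @export
read_vcf <- function(path, sample_map = NULL) {
  if (!file.exists(path)) abort("VCF not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(empty_calls())

  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2)
    abort("VCF has no genotype columns: %s", path)
  samples <- colnames(gt)[-1]
  if (!is.null(sample_map)) {
    missing <- setdiff(samples, names(sample_map))
    if (length(missing) > 0)
      abort("sample(s) absent from sample_map: %s", paste(missing, collapse = ", "))
    samples <- unname(sample_map[samples])
  }

  info_field <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, character(1))
  }
  site_dp <- suppressWarnings(as.integer(info_field(fix$INFO, "DP")))
  site_gene <- info_field(fix$INFO, "GENE")

  fmt <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  rows <- vector("list", nrow(fix) * length(samples))
  k <- 0L
  for (i in seq_len(nrow(fix))) {
    pos <- suppressWarnings(as.integer(fix$POS[i]))
    if (is.na(pos) || pos < 1)
      abort("malformed VCF record at data line %d: bad POS '%s'", i, fix$POS[i])
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    keys <- fmt[[i]]
    gt_idx <- match("GT", keys)
    ad_idx <- match("AD", keys)
    dp_idx <- match("DP", keys)
    if (is.na(gt_idx))
      abort("malformed VCF record at data line %d: FORMAT lacks GT", i)
    for (s in seq_along(samples)) {
      val <- gt[i, s + 1L]
      if (is.na(val)) next
      fields <- strsplit(val, ":", fixed = TRUE)[[1]]
      gtv <- fields[gt_idx]
      if (is.na(gtv) || gtv %in% c(".", "./.", ".|.")) next
      alleles <- suppressWarnings(as.integer(strsplit(gtv, "[/|]")[[1]]))
      alleles <- alleles[!is.na(alleles)]
      if (length(alleles) == 0 || all(alleles == 0)) next
      ad <- if (!is.na(ad_idx) && length(fields) >= ad_idx && fields[ad_idx] != ".")
        suppressWarnings(as.integer(strsplit(fields[ad_idx], ",", fixed = TRUE)[[1]]))
      else NULL
      dp <- if (!is.na(dp_idx) && length(fields) >= dp_idx && fields[dp_idx] != ".")
        suppressWarnings(as.integer(fields[dp_idx]))
      else site_dp[i]
      for (a in unique(alleles[alleles > 0])) {
        if (a > length(alts))
          abort("malformed VCF record at data line %d: GT allele %d has no ALT", i, a)
        zyg <- if (length(alleles) == 1) "HEMI"
        else if (sum(alleles == a) == 2) "HOM_ALT" else "HET"
        norm <- trim_allele(pos, fix$REF[i], alts[a])
        k <- k + 1L
        rows[[k]] <- data.frame(
          patient_id = samples[s], chrom = fix$CHROM[i], pos = norm$pos,
          ref = norm$ref, alt = norm$alt, gene = site_gene[i],
          depth = if (is.null(dp) || length(dp) == 0) NA_integer_ else dp,
          ref_depth = if (!is.null(ad) && length(ad) >= 1) ad[1] else NA_integer_,
          alt_depth = if (!is.null(ad) && length(ad) >= a + 1) ad[a + 1] else NA_integer_,
          zygosity = zyg, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0) return(empty_calls())
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(patient_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             gene = character(0), depth = integer(0), ref_depth = integer(0),
             alt_depth = integer(0), zygosity = character(0),
             stringsAsFactors = FALSE)
}

# internal: trim shared suffix then shared prefix of ref/alt, adjusting pos.
# With no external reference genome this yields the parsimonious (trimmed)
# representation; alleles must differ.
trim_allele <- function(pos, ref, alt) {
  if (ref == alt) abort("ALT equals REF at position %d", pos)
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  # suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  list(pos = pos, ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Write variant calls as a multi-sample VCF
#'
#' Emits a minimal VCF v4.2 with `GT:AD:DP` genotype fields and the gene
#' symbol in `INFO/GENE`. One record per distinct variant; samples without
#' the variant are written as `0/0`. Optionally writes `FILTER` tags from a
#' `reason` column (`PASS` when absent).
#'
#' @param calls Data frame as returned by [read_vcf()] (a `reason` column, if
#'   present, populates FILTER).
#' @param path Output path.
#' @param samples Optional character vector fixing the sample column order;
#'   defaults to the sorted patient ids present.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(calls$patient_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  lines <- character(0)
  for (k in unique(key)) {
    rows <- calls[key == k, , drop = FALSE]
    filt <- if (!is.null(rows$reason)) rows$reason[1] else "PASS"
    if (is.na(filt)) filt <- "PASS"
    gts <- rep("0/0", length(samples))
    for (j in seq_len(nrow(rows))) {
      s <- match(rows$patient_id[j], samples)
      gtv <- switch(rows$zygosity[j], HOM_ALT = "1/1", HEMI = "1", "0/1")
      ad <- if (is.na(rows$ref_depth[j]) && is.na(rows$alt_depth[j])) "."
      else paste(rows$ref_depth[j], rows$alt_depth[j], sep = ",")
      dp <- if (is.na(rows$depth[j])) "." else rows$depth[j]
      gts[s] <- paste(gtv, ad, dp, sep = ":")
    }
    info <- if (is.na(rows$gene[1])) "." else paste0("GENE=", rows$gene[1])
    lines <- c(lines, paste(c(rows$chrom[1], rows$pos[1], ".", rows$ref[1],
                              rows$alt[1], ".", filt, info, "GT:AD:DP", gts),
                            collapse = "\t"))
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
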