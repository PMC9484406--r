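#' @title Synthetic EOAD cohort generator
#' @name synthetic-cohort
#' @description
#' Generates complete, deterministic synthetic cohorts (variant calls,
#' patient metadata, knowledge and verdict tables, truth labels) with
#' planted category structure, so every pipeline stage can be tested end to
#' end without external data. Patients are assigned a latent clinical
#' category; each planted variant carries knowledge and verdict rows
#' guaranteed sufficient for that category under the classification rules,
#' and filter decoys violating exactly one selection criterion are planted
#' with their expected rejection reason. Variants live on a toy contig
#' (`chrS`) with a packaged toy region set, so no reference genome is
#' needed.
NULL

# toy gene intervals on contig chrS (0-based half-open)
SYNTH_GENES <- data.frame(
  chrom = "chrS",
  start = c(1000L, 11000L, 21000L, 31000L, 41000L, 51000L),
  end = c(9000L, 19000L, 29000L, 39000L, 49000L, 59000L),
  gene = c("PSEN1", "PSEN2", "TREM2", "MAPT", "SORL1", "APP"),
  stringsAsFactors = FALSE)

#' Toy region set for synthetic cohorts
#' @return A `region_set` over contig `chrS`.
#' @export
synthetic_region_set <- function() as_region_set(SYNTH_GENES)

#' Scenario configuration for the synthetic generator
#'
#' Defaults mirror the reference study cohort: 102 patients, 45.1% familial
#' of whom 21.7% have a strong family history, age at onset 56.88 +/- 5.84
#' years, and category fractions matching the reported carrier fractions
#' (8.8% diagnostic, 2.0% contributor, 7.8% moderate-risk, 12.7% weak-risk,
#' 7.8% APOE e4/e4; the remainder unexplained).
#'
#' @param n_patients Cohort size (default 102).
#' @param category_fractions Named numeric vector over `DIAGNOSTIC`,
#'   `CONTRIBUTOR`, `RISK_FACTOR`, `WEAK_RISK`, `APOE44`; must sum to at most
#'   1 (remainder is `UNEXPLAINED`).
#' @param familial_fraction Probability of a positive family history.
#' @param strong_given_familial Probability of a strong family history given
#'   familial.
#' @param aao_mean,aao_sd Age-at-onset distribution (years), truncated below
#'   `aao_max`.
#' @param aao_max Early-onset bound, exclusive (default 65).
#' @param depth_mean Mean sequencing depth (Poisson; planted calls are
#'   clamped to pass the depth filter).
#' @param ab_noise_sd Allele-balance noise SD around 0.5 for heterozygous
#'   calls.
#' @param ref_population_size Reference population allele denominator.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_patients = 102,
                            category_fractions = c(DIAGNOSTIC = 9 / 102,
                                                   CONTRIBUTOR = 2 / 102,
                                                   RISK_FACTOR = 8 / 102,
                                                   WEAK_RISK = 13 / 102,
                                                   APOE44 = 8 / 102),
                            familial_fraction = 46 / 102,
                            strong_given_familial = 10 / 46,
                            aao_mean = 56.88, aao_sd = 5.84, aao_max = 65,
                            depth_mean = 50, ab_noise_sd = 0.05,
                            ref_population_size = 129000L) {
  need <- c("DIAGNOSTIC", "CONTRIBUTOR", "RISK_FACTOR", "WEAK_RISK", "APOE44")
  missing <- setdiff(need, names(category_fractions))
  category_fractions[missing] <- 0
  category_fractions <- category_fractions[need]
  if (any(category_fractions < 0) || sum(category_fractions) > 1)
    abort("category fractions must be non-negative and sum to at most 1")
  if (familial_fraction < 0 || familial_fraction > 1)
    abort("familial_fraction must be a probability")
  if (category_fractions[["CONTRIBUTOR"]] > 0 &&
      familial_fraction <= category_fractions[["CONTRIBUTOR"]])
    abort(paste("infeasible scenario: contributor variants require familial",
                "carriers, but familial_fraction does not cover the",
                "CONTRIBUTOR fraction"))
  structure(list(n_patients = n_patients,
                 category_fractions = category_fractions,
                 familial_fraction = familial_fraction,
                 strong_given_familial = strong_given_familial,
                 aao_mean = aao_mean, aao_sd = aao_sd, aao_max = aao_max,
                 depth_mean = depth_mean, ab_noise_sd = ab_noise_sd,
                 ref_population_size = as.integer(ref_population_size)),
            class = "scenario_config")
}

# internal: truncated normal draw
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower | x >= upper)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower | x[bad] >= upper]
  }
  x
}

#' Generate a synthetic cohort bundle
#'
#' All randomness flows from `seed` through a single generator stream in a
#' fixed generation order (patients, then planted variants, then decoys), so
#' the same seed always yields an identical bundle.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return List of class `cohort_bundle` with data frames `patients`,
#'   `calls` (all calls including decoys), `knowledge`, `verdicts`, `truth`
#'   (latent category per patient and planted role per variant), and the
#'   `regions` set.
#' @export
generate_cohort <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  n <- config$n_patients
  ids <- sprintf("SYN%03d", seq_len(n))

  cats <- c(names(config$category_fractions), "UNEXPLAINED")
  probs <- c(config$category_fractions,
             1 - sum(config$category_fractions))
  category <- sample(cats, n, replace = TRUE, prob = probs)

  # contributors must be familial; the remaining patients draw familial
  # status at the rate that preserves the marginal familial fraction
  f_c <- config$category_fractions[["CONTRIBUTOR"]]
  p_rest <- if (f_c >= 1) 0 else (config$familial_fraction - f_c) / (1 - f_c)
  p_rest <- min(max(p_rest, 0), 1)
  familial <- ifelse(category == "CONTRIBUTOR", TRUE,
                     stats::runif(n) < p_rest)
  strong <- familial & stats::runif(n) < config$strong_given_familial
  goldman <- ifelse(!familial, "NONE",
                    ifelse(strong,
                           sample(c("S1", "S1_5"), n, replace = TRUE),
                           sample(c("S2", "S3", "S3_5"), n, replace = TRUE)))

  sex <- sample(c("M", "F"), n, replace = TRUE)
  # compensate the early-onset truncation so the realised mean age at onset
  # matches the configured mean (fixed-point on the truncated-normal mean)
  cut <- config$aao_max - 0.5  # rounding keeps every onset below aao_max
  mu <- config$aao_mean
  for (it in 1:50) {
    z <- (cut - mu) / config$aao_sd
    mu <- config$aao_mean +
      config$aao_sd * stats::dnorm(z) / stats::pnorm(z)
  }
  aao <- round(rnorm_trunc(n, mu, config$aao_sd, upper = cut))

  # APOE: e4/e4 for the APOE44 category, anything but e4/e4 otherwise
  other_gts <- c("e3/e3", "e3/e4", "e2/e3", "e2/e4", "e2/e2")
  other_p <- c(0.62, 0.27, 0.075, 0.025, 0.01)
  apoe <- ifelse(category == "APOE44", "e4/e4",
                 sample(other_gts, n, replace = TRUE, prob = other_p))
  snps <- apoe_to_snps(apoe)

  patients <- data.frame(patient_id = ids, sex = sex, age_at_onset = aao,
                         goldman_score = goldman,
                         rs429358_gt = snps$rs429358_gt,
                         rs7412_gt = snps$rs7412_gt,
                         stringsAsFactors = FALSE)

  # ---- planted variants ----------------------------------------------
  gene_for <- c(DIAGNOSTIC = "PSEN1", CONTRIBUTOR = "PSEN2",
                RISK_FACTOR = "TREM2", WEAK_RISK = "MAPT")
  regions <- synthetic_region_set()
  pos_counter <- stats::setNames(SYNTH_GENES$start + 10L, SYNTH_GENES$gene)
  next_pos <- function(gene) {
    p <- pos_counter[[gene]]
    pos_counter[[gene]] <<- p + 13L
    p + 1L  # 1-based VCF position inside the interval
  }
  bases <- c("A", "C", "G", "T")

  calls <- list(); knowledge <- list(); verdicts <- list(); troles <- list()
  add_variant <- function(pid, gene, clinvar, hgmd, novel_lp, role,
                          ref_alt = NA_integer_) {
    pos <- next_pos(gene)
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    hgvs <- sprintf("c.%d%s>%s", pos - SYNTH_GENES$start[SYNTH_GENES$gene == gene],
                    ref, alt)
    depth <- max(stats::rpois(1, config$depth_mean), 10L)
    ab <- rnorm_trunc(1, 0.5, config$ab_noise_sd, lower = 0.3, upper = 0.7)
    # clamp so integer rounding cannot push the realised balance outside
    # the default selection band
    alt_depth <- as.integer(min(max(round(depth * ab), ceiling(0.30 * depth)),
                                floor(0.70 * depth)))
    calls[[length(calls) + 1L]] <<- data.frame(
      patient_id = pid, chrom = "chrS", pos = pos, ref = ref, alt = alt,
      gene = gene, depth = depth, ref_depth = depth - alt_depth,
      alt_depth = alt_depth, zygosity = "HET", stringsAsFactors = FALSE)
    gnomad <- if (is.na(ref_alt)) "NR"
    else paste0(ref_alt, "/", config$ref_population_size)
    knowledge[[length(knowledge) + 1L]] <<- data.frame(
      gene = gene, patient_id = pid, hgvs_c = hgvs,
      hgvs_p = sprintf("p.Xaa%dYaa", pos %% 997L),
      zygosity = "HET",
      clinvar_class = if (novel_lp) "NR" else clinvar,
      conflicting_detail = NA_character_,
      hgmd_phenotype = if (novel_lp) "NR" else hgmd,
      prediction = NA_character_, gnomad_nfe = gnomad,
      app_exon = NA_integer_, literature_flags = NA_character_,
      chrom = "chrS", pos = pos, ref = ref, alt = alt,
      stringsAsFactors = FALSE)
    if (novel_lp) {
      for (tool in CONSENSUS_TOOLS$MISSENSE)
        verdicts[[length(verdicts) + 1L]] <<- data.frame(
          gene = gene, hgvs_c = hgvs, tool = tool, verdict = "DAMAGING",
          stringsAsFactors = FALSE)
    }
    troles[[length(troles) + 1L]] <<- data.frame(
      chrom = "chrS", pos = pos, ref = ref, alt = alt, gene = gene,
      hgvs_c = hgvs, patient_id = pid, role = role, stringsAsFactors = FALSE)
  }

  for (i in seq_len(n)) {
    cat_i <- category[i]
    if (cat_i == "DIAGNOSTIC") {
      # alternate known-pathogenic and novel consensus-LP causative variants
      if (i %% 2 == 0) {
        add_variant(ids[i], "PSEN1", "Pathogenic", "Alzheimer disease",
                    novel_lp = FALSE, role = "DIAGNOSTIC")
      } else {
        add_variant(ids[i], "PSEN1", "NR", "NR",
                    novel_lp = TRUE, role = "DIAGNOSTIC")
      }
    } else if (cat_i == "CONTRIBUTOR") {
      add_variant(ids[i], "PSEN2", "VUS", "Alzheimer disease?",
                  novel_lp = FALSE, role = "CONTRIBUTOR", ref_alt = 1L)
    } else if (cat_i == "RISK_FACTOR") {
      add_variant(ids[i], "TREM2", "VUS", "Alzheimer disease?",
                  novel_lp = FALSE, role = "RISK_FACTOR")
    } else if (cat_i == "WEAK_RISK") {
      add_variant(ids[i], "MAPT", "VUS", "NR",
                  novel_lp = FALSE, role = "WEAK_RISK")
    } else if (stats::runif(1) < 0.5) {
      # half the remaining patients carry an inert benign variant
      add_variant(ids[i], "SORL1", "Benign", "NR",
                  novel_lp = FALSE, role = "BENIGN")
    }
  }

  # ---- filter decoys --------------------------------------------------
  decoys <- plant_filter_decoys(config, ids)
  calls <- c(calls, list(decoys$calls))
  knowledge <- c(knowledge, list(decoys$knowledge))
  troles <- c(troles, list(decoys$truth))

  bundle <- list(
    patients = patients,
    calls = do.call(rbind, calls),
    knowledge = do.call(rbind, knowledge),
    verdicts = if (length(verdicts) > 0) do.call(rbind, verdicts)
    else data.frame(gene = character(0), hgvs_c = character(0),
                    tool = character(0), verdict = character(0)),
    truth = list(patients = data.frame(patient_id = ids, category = category,
                                       familial = familial,
                                       stringsAsFactors = FALSE),
                 variants = do.call(rbind, troles)),
    regions = regions, config = config, seed = seed)
  rownames(bundle$calls) <- rownames(bundle$knowledge) <- NULL
  class(bundle) <- "cohort_bundle"
  bundle
}

#' Plant one decoy call per filter criterion
#'
#' Each decoy violates exactly one selection criterion (region, depth,
#' allelic balance, MAF) and is truth-labelled with the expected rejection
#' reason.
#'
#' @param config A [scenario_config()].
#' @param patient_ids Patient identifiers to host the decoys (recycled).
#' @return List with `calls`, `knowledge` and `truth` data frames.
#' @export
plant_filter_decoys <- function(config = scenario_config(),
                                patient_ids = "SYN001") {
  pid <- rep_len(patient_ids, 4)
  depth_ok <- max(stats::rpois(1, config$depth_mean), 10L)
  # decoy allele balance below the lower bound even after integer rounding
  ab_bad <- stats::runif(1, 0.05, 0.25)
  alt_bad <- max(1L, as.integer(floor(depth_ok * ab_bad)))
  balanced_alt <- as.integer(round(depth_ok / 2))
  maf_alt <- as.integer(0.05 * config$ref_population_size)
  calls <- data.frame(
    patient_id = pid,
    chrom = "chrS",
    # decoy 1 sits left of every interval (flank included); 2-4 inside TREM2
    pos = c(100L, 28100L, 28200L, 28300L),
    ref = "A", alt = "G",
    gene = "TREM2",
    depth = c(depth_ok, 9L, depth_ok, depth_ok),
    ref_depth = c(depth_ok - balanced_alt, 4L,
                  depth_ok - alt_bad, depth_ok - balanced_alt),
    alt_depth = c(balanced_alt, 5L, alt_bad, balanced_alt),
    zygosity = "HET", stringsAsFactors = FALSE)
  knowledge <- data.frame(
    gene = calls$gene, patient_id = pid, hgvs_c = sprintf("c.dec%d", 1:4),
    hgvs_p = NA_character_, zygosity = "HET",
    clinvar_class = "VUS", conflicting_detail = NA_character_,
    hgmd_phenotype = "NR", prediction = NA_character_,
    gnomad_nfe = c("NR", "NR", "NR",
                   paste0(maf_alt, "/", config$ref_population_size)),
    app_exon = NA_integer_, literature_flags = NA_character_,
    chrom = calls$chrom, pos = calls$pos, ref = calls$ref, alt = calls$alt,
    stringsAsFactors = FALSE)
  truth <- data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
                      alt = calls$alt, gene = calls$gene,
                      hgvs_c = knowledge$hgvs_c, patient_id = pid,
                      role = paste0("decoy_", c("region", "depth",
                                                "allelic_balance", "maf")),
                      stringsAsFactors = FALSE)
  list(calls = calls, knowledge = knowledge, truth = truth)
}

# internal: APOE genotype -> SNP genotypes (inverse of the haplotype map)
apoe_to_snps <- function(genotype) {
  hap <- list(e1 = c("C", "T"), e2 = c("T", "T"),
              e3 = c("T", "C"), e4 = c("C", "C"))
  parts <- strsplit(apoe_normalise(genotype), "/", fixed = TRUE)
  rs429358 <- vapply(parts, function(p)
    paste(sort(c(hap[[p[1]]][1], hap[[p[2]]][1])), collapse = "/"), character(1))
  rs7412 <- vapply(parts, function(p)
    paste(sort(c(hap[[p[1]]][2], hap[[p[2]]][2])), collapse = "/"), character(1))
  data.frame(rs429358_gt = rs429358, rs7412_gt = rs7412,
             stringsAsFactors = FALSE)
}

#' Write a cohort bundle to disk
#'
#' Emits `cohort.vcf`, `patients.tsv`, `knowledge.tsv`, `verdicts.tsv`,
#' `truth_patients.tsv`, `truth_variants.tsv` and `regions.tsv` under `dir`.
#' The bundle is directly consumable by [run_triage()].
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(bundle$calls, file.path(dir, "cohort.vcf"),
            samples = bundle$patients$patient_id)
  write_tsv(bundle$patients, file.path(dir, "patients.tsv"))
  write_tsv(bundle$knowledge, file.path(dir, "knowledge.tsv"))
  write_tsv(bundle$verdicts, file.path(dir, "verdicts.tsv"))
  write_tsv(bundle$truth$patients, file.path(dir, "truth_patients.tsv"))
  write_tsv(bundle$truth$variants, file.path(dir, "truth_variants.tsv"))
  write_region_set(bundle$regions, file.path(dir, "regions.tsv"))
  invisible(dir)
}

#' Read a cohort bundle written by [write_bundle()]
#' @param dir Bundle directory.
#' @return A `cohort_bundle` (calls re-read from the VCF).
#' @export
read_bundle <- function(dir) {
  bundle <- list(
    patients = read_tsv_strict(file.path(dir, "patients.tsv"),
                               c("patient_id", "goldman_score")),
    calls = read_vcf(file.path(dir, "cohort.vcf")),
    knowledge = read_tsv_strict(file.path(dir, "knowledge.tsv"),
                                c("gene", "hgvs_c", "clinvar_class")),
    verdicts = read_tsv_strict(file.path(dir, "verdicts.tsv"), character()),
    truth = list(
      patients = read_tsv_strict(file.path(dir, "truth_patients.tsv"),
                                 c("patient_id", "category")),
      variants = read_tsv_strict(file.path(dir, "truth_variants.tsv"),
                                 c("pos", "role"))),
    regions = read_region_set(file.path(dir, "regions.tsv")))
  class(bundle) <- "cohort_bundle"
  bundle
}
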