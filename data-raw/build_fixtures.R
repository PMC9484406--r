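# Builds the synthetic fixture files under inst/extdata:
#  - cohort_metadata_synthetic.tsv: a synthetic per-patient completion of the
#    102-patient cohort. Family-history scores printed for patient IDs in the
#    packaged variant tables are honoured verbatim; the remaining patients are
#    filled deterministically to reach the published totals (46 familial of
#    whom 10 strong, 49 male) and APOE genotype distribution (8 e4/e4 none of
#    whom carry causative-gene variants, 7 of them familial and 2 strong;
#    30 e3/e4; 2 e2/e4).
#  - predictor_verdicts_synthetic.tsv: per-tool verdicts consistent with each
#    novel variant's published consensus prediction.
# Run from the package root: Rscript data-raw/build_fixtures.R

devtools::load_all(".", quiet = TRUE)
set.seed(20261001)

extdata <- "inst/extdata"
tables <- file.path(extdata, c("table_causative_variants.tsv",
                               "table_trem2_variants.tsv",
                               "table_other_dementia_variants.tsv",
                               "table_ad_risk_variants.tsv",
                               "table_gwas_variants.tsv"))
rows <- do.call(rbind, lapply(tables, function(p)
  utils::read.delim(p, na.strings = c("."), stringsAsFactors = FALSE)))

# ---- printed family-history scores, with consistency check ---------------
printed <- unique(rows[, c("patient_id", "fh_score")])
stopifnot(!anyDuplicated(printed$patient_id))
ids <- sprintf("AD#%03d", 1:102)
stopifnot(all(printed$patient_id %in% ids))

score <- setNames(rep(NA_real_, 102), ids)
score[printed$patient_id] <- printed$fh_score

n_strong_printed <- sum(score %in% c(1, 1.5))
n_moderate_printed <- sum(score %in% c(2, 3, 3.5))
n_sporadic_printed <- sum(score == 0, na.rm = TRUE)
unprinted <- ids[is.na(score)]
cat(sprintf("printed: %d strong, %d moderate, %d sporadic; %d unprinted\n",
            n_strong_printed, n_moderate_printed, n_sporadic_printed,
            length(unprinted)))

# fill to Table-1 totals: 10 strong, 36 moderate, 56 sporadic
need_strong <- 10 - n_strong_printed
need_moderate <- 36 - n_moderate_printed
need_sporadic <- 56 - n_sporadic_printed
stopifnot(need_strong >= 0, need_moderate >= 0, need_sporadic >= 0,
          need_strong + need_moderate + need_sporadic == length(unprinted))
fill <- sample(unprinted)
fill_strong <- fill[seq_len(need_strong)]
fill_moderate <- fill[need_strong + seq_len(need_moderate)]
fill_sporadic <- setdiff(fill, c(fill_strong, fill_moderate))
score[fill_strong] <- sample(c(1, 1.5), need_strong, replace = TRUE)
score[fill_moderate] <- sample(c(2, 3, 3.5), need_moderate, replace = TRUE)
score[fill_sporadic] <- 0

# ---- APOE ----------------------------------------------------------------
causative_carriers <- unique(rows$patient_id[rows$gene %in%
                                               c("APP", "PSEN1", "PSEN2")])
familial_ids <- ids[score[ids] > 0]
strong_ids <- ids[score[ids] %in% c(1, 1.5)]
# e4/e4: 2 strong + 5 moderate + 1 sporadic, all outside causative carriers
elig_strong <- setdiff(strong_ids, causative_carriers)
elig_moderate <- setdiff(setdiff(familial_ids, strong_ids), causative_carriers)
elig_sporadic <- setdiff(ids[score[ids] == 0], causative_carriers)
apoe44 <- c(sample(elig_strong, 2), sample(elig_moderate, 5),
            sample(elig_sporadic, 1))

apoe <- setNames(rep(NA_character_, 102), ids)
apoe[apoe44] <- "e4/e4"
rest <- sample(setdiff(ids, apoe44))
apoe[rest[1:30]] <- "e3/e4"
apoe[rest[31:32]] <- "e2/e4"
apoe[rest[33:92]] <- "e3/e3"
apoe[rest[93:length(rest)]] <- "e2/e3"

snps <- eoadtriage:::apoe_to_snps(apoe[ids])

# ---- demographics --------------------------------------------------------
sex <- sample(c(rep("M", 49), rep("F", 53)))
aao <- round(pmin(stats::rnorm(102, 56.88, 5.84), 64))
aao[sample(102, 10)] <- sample(44:50, 10, replace = TRUE)  # 10 onsets < 51
ptau <- round(stats::runif(102, 0.12, 0.35), 3)
ab <- round(stats::runif(102, 0.30, 0.60), 3)

meta <- data.frame(patient_id = ids, sex = sex, age_at_onset = aao,
                   goldman_score = score[ids],
                   rs429358_gt = snps$rs429358_gt,
                   rs7412_gt = snps$rs7412_gt,
                   ptau_ab42_ratio = ptau, ab42_ab40_ratio = ab)
utils::write.table(meta, file.path(extdata, "cohort_metadata_synthetic.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE, na = ".")

# ---- predictor verdicts --------------------------------------------------
novel <- rows[rows$clinvar_class == "NR" & rows$hgmd_phenotype == "NR", ]
novel <- unique(novel[, c("gene", "hgvs_c", "hgvs_p", "prediction")])
stopifnot(!anyNA(novel$prediction))
verdicts <- do.call(rbind, lapply(seq_len(nrow(novel)), function(i) {
  eff <- infer_effect_class(novel$hgvs_c[i], novel$hgvs_p[i])
  tools <- CONSENSUS_TOOLS[[eff]]
  v <- if (novel$prediction[i] == "likely_pathogenic")
    rep("DAMAGING", length(tools))
  else c("DAMAGING", rep("TOLERATED", length(tools) - 1))
  data.frame(gene = novel$gene[i], hgvs_c = novel$hgvs_c[i],
             tool = tools, verdict = v)
}))
utils::write.table(verdicts,
                   file.path(extdata, "predictor_verdicts_synthetic.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE, na = ".")
cat(sprintf("wrote %d patients, %d verdict rows (%d novel variants)\n",
            nrow(meta), nrow(verdicts), nrow(novel)))
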