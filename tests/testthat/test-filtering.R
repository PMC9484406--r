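base_call <- function(...) {
  defaults <- list(patient_id = "P1", chrom = "chrS", pos = 2000L,
                   ref = "A", alt = "G", gene = "PSEN1", depth = 30L,
                   ref_depth = 15L, alt_depth = 15L, zygosity = "HET",
                   ref_af = NA_real_)
  args <- list(...)
  defaults[names(args)] <- args
  do.call(data.frame, c(defaults, stringsAsFactors = FALSE))
}

test_that("allelic balance is the alt fraction of informative reads", {
  expect_equal(allelic_balance(12, 8), 0.4)
  expect_equal(allelic_balance(0, 30), 1.0)
  expect_true(is.na(allelic_balance(NA, 8)))
  expect_true(is.na(allelic_balance(0, 0)))
})

test_that("filter config validates its bounds", {
  expect_error(filter_config(min_depth = 0), "min_depth")
  expect_error(filter_config(ab_min = 0.8, ab_max = 0.7), "ab_min")
  expect_error(filter_config(max_maf = 0), "max_maf")
})

test_that("depth, balance and rarity criteria reject as specified", {
  cfg <- filter_config()
  expect_equal(apply_filters(base_call(depth = 9L), cfg)$rejected$reason, "depth")
  expect_equal(nrow(apply_filters(base_call(depth = 10L), cfg)$rejected), 0)

  # allelic-balance bounds are inclusive: enumerate around both edges
  for (ab in c(0.29, 0.30, 0.70, 0.71)) {
    call <- base_call(depth = 100L, alt_depth = as.integer(ab * 100),
                      ref_depth = as.integer(100 - ab * 100))
    res <- apply_filters(call, cfg)
    if (ab >= 0.30 && ab <= 0.70) {
      expect_equal(nrow(res$kept), 1, info = ab)
    } else {
      expect_equal(res$rejected$reason, "allelic_balance", info = ab)
    }
  }
  # the balance filter only applies to heterozygous calls
  hom <- base_call(zygosity = "HOM_ALT", ref_depth = 0L, alt_depth = 30L)
  expect_equal(nrow(apply_filters(hom, cfg)$kept), 1)

  # absent from the reference population counts as frequency 0 and passes
  expect_equal(nrow(apply_filters(base_call(ref_af = NA), cfg)$kept), 1)
  expect_equal(apply_filters(base_call(ref_af = 0.02), cfg)$rejected$reason, "maf")
  expect_equal(nrow(apply_filters(base_call(ref_af = 0.0099), cfg)$kept), 1)

  # missing depth rejected by default, kept when configured
  miss <- base_call(depth = NA_integer_, ref_depth = NA_integer_,
                    alt_depth = NA_integer_)
  expect_equal(apply_filters(miss, cfg)$rejected$reason, "missing_quality")
  keep_cfg <- filter_config(keep_missing_quality = TRUE)
  expect_equal(nrow(apply_filters(miss, keep_cfg)$kept), 1)
})

test_that("region filter respects the flanking margin and fires first", {
  regions <- as_region_set(data.frame(chrom = "chrS", start = 1000L,
                                      end = 2000L, gene = "PSEN1"))
  cfg <- filter_config(flank_bp = 7)
  # 1-based position 2007 is the last flanking base (0-based 2006 < 2000+7)
  expect_equal(nrow(apply_filters(base_call(pos = 2007L), cfg, regions)$kept), 1)
  expect_equal(apply_filters(base_call(pos = 2008L), cfg, regions)$rejected$reason,
               "region")
  expect_equal(nrow(apply_filters(base_call(pos = 994L), cfg, regions)$kept), 1)
  expect_equal(apply_filters(base_call(pos = 993L), cfg, regions)$rejected$reason,
               "region")
  # first failed criterion wins: out-of-region AND low depth reports region
  bad <- base_call(pos = 100L, depth = 5L)
  expect_equal(apply_filters(bad, cfg, regions)$rejected$reason, "region")
})

test_that("filtering partitions its input, is idempotent and order-independent", {
  cfg <- filter_config()
  for (seed in 1:25) {
    calls <- random_calls(40, seed = seed)
    res <- apply_filters(calls, cfg)
    expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(calls))
    # idempotent: re-filtering the kept set keeps everything
    again <- apply_filters(res$kept, cfg)
    expect_equal(again$kept, res$kept)
    expect_equal(nrow(again$rejected), 0)
    # order-independent
    perm <- sample(nrow(calls))
    res2 <- apply_filters(calls[perm, ], cfg)
    key <- function(df) sort(paste(df$patient_id, df$pos, df$depth, df$alt_depth))
    expect_equal(key(res2$kept), key(res$kept))
  }
})

test_that("distinct-variant counting collapses shared carriers", {
  calls <- rbind(base_call(patient_id = "P1"), base_call(patient_id = "P2"))
  expect_equal(count_distinct_variants(calls), 1)
  expect_equal(count_distinct_variants(calls[0, ]), 0)
  expect_equal(count_distinct_variants(calls, genes = "TREM2"), 0)
})
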