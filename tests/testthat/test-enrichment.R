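test_that("two-sided Fisher handles degenerate and symmetric tables", {
  expect_equal(fisher_exact_two_sided(0, 204, 0, 129100), 1)
  expect_equal(fisher_exact_two_sided(2, 8, 2, 8), 1)
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher p-values match brute-force enumeration on random tables", {
  set.seed(42)
  for (i in 1:200) {
    tab <- rpois(4, 6)
    p <- fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p, oracle_fisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    # swapping the two rows leaves the p-value unchanged
    expect_equal(p, fisher_exact_two_sided(tab[3], tab[4], tab[1], tab[2]),
                 tolerance = 1e-12)
  }
})

test_that("Fisher p-values agree with stats::fisher.test", {
  set.seed(7)
  for (i in 1:60) {
    tab <- c(rpois(2, 4), rpois(2, 40))
    if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0 ||
        sum(tab[c(1, 3)]) == 0 || sum(tab[c(2, 4)]) == 0) next
    ours <- fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4])
    ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  # a cohort-scale example: 2 of 204 alleles vs 44 of 129182
  expect_equal(fisher_exact_two_sided(2, 202, 44, 129138),
               stats::fisher.test(matrix(c(2, 202, 44, 129138), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH satisfies the step-up identities on random p-vectors", {
  set.seed(11)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # agrees with the naive double-loop oracle
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # monotone: sorting inputs sorts outputs
    expect_equal(bh_adjust(sort(p)), sort(q), tolerance = 1e-12)
  }
})

test_that("cohort allele tables count alt alleles by zygosity", {
  at <- enrich_variant("HET", 102, 4L, 129100L)
  expect_equal(at$cohort_alt, 1)
  expect_equal(at$cohort_total, 204)
  expect_equal(at$ref_alt, 4)
  expect_equal(enrich_variant(c("HET", "HET"), 102, 44L, 129182L)$cohort_alt, 2)
  hom <- enrich_variant("HOM_ALT", 10, 1L, 1000L)
  expect_equal(hom$cohort_alt, 2)
  expect_equal(hom$cohort_total, 20)
  hemi <- enrich_variant(c("HEMI", "HET"), 10, 1L, 1000L)
  expect_equal(hemi$cohort_alt, 2)
  expect_equal(hemi$cohort_total, 19)
  # not reported in the reference: excluded from testing
  expect_false(enrich_variant("HET", 102, NA, NA)$testable)
  expect_error(enrich_variant(c("HET", "HET"), 1, 1L, 100L), "more carriers")
})

test_that("enrichment over the causative table flags only Met174Val", {
  res <- packaged_pipeline()
  v <- res$variants[res$variants$table == "causative", ]
  testable <- v[v$testable, ]
  expect_equal(nrow(testable), 8)
  expect_true(all(testable$family_size == 8))
  expect_true(all(testable$adj_p >= testable$raw_p))
  # independent oracle for the whole family
  raw_oracle <- mapply(function(a, at, c, ct)
    stats::fisher.test(matrix(c(a, at - a, c, ct - c), 2, byrow = TRUE))$p.value,
    testable$cohort_alt, testable$cohort_total,
    testable$ref_alt, testable$ref_total)
  expect_equal(testable$raw_p, unname(raw_oracle), tolerance = 1e-9)
  expect_equal(testable$adj_p, unname(stats::p.adjust(raw_oracle, "BH")),
               tolerance = 1e-9)
  sig <- testable[testable$adj_p < 0.05, ]
  # Met174Val (2 familial-cohort carriers vs 44/129182) clears FDR 0.05;
  # the other significant raw p-values belong to diagnostic variants
  expect_true("c.520A>G" %in% sig$hgvs_c)
  # untestable variants carry no p-values
  expect_true(all(is.na(v$adj_p[!v$testable])))
})
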