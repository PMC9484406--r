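verdict_set <- function(tools, damaging) {
  v <- rep("TOLERATED", length(tools))
  v[seq_len(damaging)] <- "DAMAGING"
  names(v) <- tools
  v
}

test_that("missense consensus needs at least three of four damaging calls", {
  tools <- CONSENSUS_TOOLS$MISSENSE
  # enumerate all 2^4 verdict patterns against the threshold
  for (mask in 0:15) {
    v <- ifelse(bitwAnd(mask, 2^(0:3)) > 0, "DAMAGING", "TOLERATED")
    names(v) <- tools
    res <- consensus_classify("MISSENSE", v, gene = "PSEN1")
    expected <- if (sum(v == "DAMAGING") >= 3) "LIKELY_PATHOGENIC" else "LIKELY_BENIGN"
    expect_equal(res$label, expected, info = mask)
    expect_equal(res$votes_damaging, sum(v == "DAMAGING"))
  }
  # NO_CALL counts as not damaging
  v <- verdict_set(tools, 3)
  v[4] <- "NO_CALL"
  expect_equal(consensus_classify("MISSENSE", v, gene = "PSEN1")$label,
               "LIKELY_PATHOGENIC")
  v[3] <- "NO_CALL"
  expect_equal(consensus_classify("MISSENSE", v, gene = "PSEN1")$label,
               "LIKELY_BENIGN")
})

test_that("three-tool splice and silent classes use simple majority", {
  for (eff in c("SPLICE_REGION", "SILENT")) {
    tools <- CONSENSUS_TOOLS[[eff]]
    for (d in 0:3) {
      res <- consensus_classify(eff, verdict_set(tools, d), gene = "SORL1")
      expect_equal(res$label,
                   if (d >= 2) "LIKELY_PATHOGENIC" else "LIKELY_BENIGN",
                   info = paste(eff, d))
    }
  }
})

test_that("the APP positional rule dominates all verdict patterns", {
  tools <- CONSENSUS_TOOLS$MISSENSE
  for (mask in 0:15) {
    v <- ifelse(bitwAnd(mask, 2^(0:3)) > 0, "DAMAGING", "TOLERATED")
    names(v) <- tools
    res <- consensus_classify("MISSENSE", v, gene = "APP", app_exon = 5)
    expect_equal(res$label, "LIKELY_BENIGN")
    expect_equal(res$rule_applied, "app_outside_exon_16_17")
  }
  # inside the amyloid-coding exons the votes decide
  v <- verdict_set(tools, 4)
  expect_equal(consensus_classify("MISSENSE", v, gene = "APP",
                                  app_exon = 17)$label, "LIKELY_PATHOGENIC")
  expect_error(consensus_classify("MISSENSE", v, gene = "APP"), "app_exon")
})

test_that("consensus is monotone and order-independent in its verdicts", {
  tools <- CONSENSUS_TOOLS$MISSENSE
  rank <- c(LIKELY_BENIGN = 0, LIKELY_PATHOGENIC = 1)
  for (mask in 0:15) {
    v <- ifelse(bitwAnd(mask, 2^(0:3)) > 0, "DAMAGING", "TOLERATED")
    names(v) <- tools
    base <- consensus_classify("MISSENSE", v, gene = "PSEN1")$label
    # flipping any single verdict to DAMAGING never demotes the label
    for (i in which(v == "TOLERATED")) {
      v2 <- v
      v2[i] <- "DAMAGING"
      up <- consensus_classify("MISSENSE", v2, gene = "PSEN1")$label
      expect_gte(rank[up], rank[base])
    }
    # permuting the verdict vector changes nothing
    perm <- sample(length(v))
    expect_equal(consensus_classify("MISSENSE", v[perm], gene = "PSEN1")$label,
                 base)
  }
})

test_that("a verdict set from the wrong tool panel is rejected", {
  expect_error(
    consensus_classify("SILENT", verdict_set(CONSENSUS_TOOLS$MISSENSE, 2),
                       gene = "PSEN1"),
    "does not match")
  bad <- verdict_set(CONSENSUS_TOOLS$MISSENSE, 1)
  bad[1] <- "MAYBE"
  expect_error(consensus_classify("MISSENSE", bad, gene = "PSEN1"), "verdicts")
})

test_that("consensus labels over the curated tables match the published calls", {
  res <- packaged_pipeline()
  v <- res$variants
  # five never-reported likely-pathogenic variants in CCNF, DCTN1, NOTCH3
  expect_equal(count_consensus_label(v, "LIKELY_PATHOGENIC",
                                     c("CCNF", "DCTN1", "NOTCH3")), 5)
  # four CSF1R variants predicted likely benign
  expect_equal(count_consensus_label(v, "LIKELY_BENIGN", "CSF1R"), 4)
  expect_equal(count_consensus_label(v[0, ], "LIKELY_PATHOGENIC"), 0)
  # consensus labels agree with the printed predictions everywhere
  novel <- v[v$novel & !is.na(v$prediction), ]
  expect_gt(nrow(novel), 40)
  expect_equal(tolower(novel$consensus_label),
               ifelse(novel$gene == "APP" & !novel$app_exon %in% c(16, 17),
                      "likely_benign", novel$prediction))
})
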