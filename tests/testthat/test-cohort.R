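test_that("Goldman strength is a total three-way partition of the score enum", {
  expect_equal(goldman_strength("S1"), "STRONG")
  expect_equal(goldman_strength("S3_5"), "MODERATE")
  expect_equal(goldman_strength("NONE"), "SPORADIC")
  # every enum member maps to exactly one stratum
  strata <- goldman_strength(GOLDMAN_SCORES)
  expect_false(anyNA(strata))
  expect_equal(sum(strata == "STRONG"), 2)
  expect_equal(sum(strata == "MODERATE"), 3)
  expect_equal(sum(strata == "SPORADIC"), 1)
  expect_error(goldman_strength("S4"), "S4")
})

test_that("numeric-dialect Goldman scores parse to canonical labels", {
  expect_equal(parse_goldman_score(c("0", "1", "1.5", "2", "3", "3.5")),
               c("NONE", "S1", "S1_5", "S2", "S3", "S3_5"))
  expect_equal(parse_goldman_score(3.5), "S3_5")
  expect_error(parse_goldman_score("2.5"), "2.5")
})

test_that("CSF AD profile uses strict inequalities on both cutoffs", {
  expect_true(csf_ad_profile(0.20, 0.50))
  # boundary cases fail the strict comparisons
  expect_false(csf_ad_profile(0.108, 0.50))
  expect_false(csf_ad_profile(0.20, 0.68))
  # full truth table around the cutoffs
  for (pt in c(0.107, 0.108, 0.109)) {
    for (ab in c(0.679, 0.68, 0.681)) {
      expect_equal(csf_ad_profile(pt, ab), pt > 0.108 && ab < 0.68)
    }
  }
  # missing ratios are indeterminate, not FALSE
  expect_true(is.na(csf_ad_profile(NA, 0.5)))
  expect_error(csf_ad_profile(-0.1, 0.5), "positive")
})

test_that("APOE from SNPs agrees with exhaustive haplotype enumeration", {
  expect_equal(apoe_from_snps("T/T", "C/C")$genotype, "e3/e3")
  expect_equal(apoe_from_snps("C/C", "C/C")$genotype, "e4/e4")

  # oracle: enumerate both phasings of every unordered genotype pair against
  # the 4-haplotype table and collect the compatible epsilon genotypes
  hap <- function(x429358, x7412) {
    if (x429358 == "T" && x7412 == "C") "e3"
    else if (x429358 == "T" && x7412 == "T") "e2"
    else if (x429358 == "C" && x7412 == "C") "e4"
    else "e1"
  }
  gts <- c("C/C", "C/T", "T/T")
  for (g1 in gts) {
    for (g2 in gts) {
      a <- strsplit(g1, "/")[[1]]
      b <- strsplit(g2, "/")[[1]]
      phasings <- unique(list(
        sort(c(hap(a[1], b[1]), hap(a[2], b[2]))),
        sort(c(hap(a[1], b[2]), hap(a[2], b[1])))))
      got <- apoe_from_snps(g1, g2)
      expect_true(list(c(got$allele1, got$allele2)) %in% phasings,
                  info = paste(g1, g2))
      if (length(phasings) > 1) {
        # phase-ambiguous double heterozygote: e2/e4 by convention, flagged
        expect_true(got$ambiguous)
        expect_equal(got$genotype, "e2/e4")
      } else {
        expect_false(got$ambiguous)
      }
    }
  }
  expect_error(apoe_from_snps("A/T", "C/C"), "rs429358")
})

test_that("APOE category counts partition the cohort", {
  expect_equal(count_apoe_categories(c("e4/e4", "e3/e4", "e2/e4", "e3/e3")),
               list(e4_homozygous = 1, e4_heterozygous = 2, other = 1,
                    unknown = 0))
  counts <- count_apoe_categories(c(rep("e4/e4", 8), rep("e3/e4", 30),
                                    rep("e2/e4", 2), rep("e3/e3", 62)))
  expect_equal(counts$e4_homozygous, 8)
  expect_equal(counts$e4_heterozygous, 32)
  expect_equal(counts$other, 62)
  expect_equal(count_apoe_categories(character(0)),
               list(e4_homozygous = 0, e4_heterozygous = 0, other = 0,
                    unknown = 0))
  # unknown genotypes are bucketed, never dropped
  mixed <- count_apoe_categories(c("e4/e4", NA, "e3/e3"))
  expect_equal(mixed$unknown, 1)
  expect_equal(Reduce(`+`, mixed), 3)
})

test_that("patient metadata reader derives strata and APOE, enforcing bounds", {
  meta <- read_patient_metadata(eoad_fixture_path("cohort_metadata_synthetic.tsv"))
  expect_equal(nrow(meta), 102)
  expect_equal(sum(meta$familial), 46)
  expect_equal(sum(meta$fh_strength == "STRONG"), 10)
  expect_equal(sum(meta$sex == "M"), 49)
  expect_true(all(meta$age_at_onset < 65))
  expect_equal(count_apoe_categories(meta$apoe_genotype)$e4_homozygous, 8)

  bad <- data.frame(patient_id = "P1", sex = "M", age_at_onset = 70,
                    goldman_score = "0")
  f <- tempfile(fileext = ".tsv")
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_patient_metadata(f), "early-onset")
})
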