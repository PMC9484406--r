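# Independent oracles used to validate the statistics implementations.

# Brute-force two-sided Fisher exact test: enumerate every 2x2 table with the
# observed margins, computing point probabilities directly from binomial
# coefficients, and sum those not exceeding the observed table's probability
# (point-probability / minimum-likelihood convention).
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
}

# Naive Benjamini-Hochberg step-up: q_i = min over j with p_j >= p_i of
# p_(j) * m / rank(j), computed by explicit double loop.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1)), 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Random call table for filter property tests.
random_calls <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depth <- sample(c(NA, 5:60), n, replace = TRUE)
  ab <- runif(n)
  alt <- ifelse(is.na(depth), NA, round(depth * ab))
  data.frame(
    patient_id = sample(sprintf("P%02d", 1:10), n, replace = TRUE),
    chrom = "chrS",
    pos = sample(1500:8500, n, replace = TRUE),
    ref = "A", alt = "G",
    gene = "PSEN1",
    depth = depth,
    ref_depth = ifelse(is.na(depth), NA, depth - alt),
    alt_depth = alt,
    zygosity = sample(c("HET", "HOM_ALT"), n, replace = TRUE, prob = c(.8, .2)),
    ref_af = sample(c(NA, 0, 1e-5, 5e-3, 0.02, 0.2), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

packaged_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_packaged_fixtures()
    cache
  }
})

CAUSATIVE_GENES <- c("APP", "PSEN1", "PSEN2")
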