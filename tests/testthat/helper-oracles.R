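# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force pair counting and hand-rolled
# cumulative tables.

# Bin-free pairwise AUC: P(conf_correct > conf_incorrect) + 0.5 P(tie),
# by explicit pair enumeration.
oracle_pairwise_auc <- function(correct, confidence) {
  cc <- confidence[correct]
  ci <- confidence[!correct]
  tot <- 0
  for (a in cc) tot <- tot + sum(a > ci) + 0.5 * sum(a == ci)
  tot / (as.numeric(length(cc)) * length(ci))
}

# Brute-force type-2 ROC from explicit cumulative counts over given bin
# labels (k = most confident), anchored at (0,0); trapezoid by loop.
oracle_binned_auc <- function(correct, bins, k) {
  fa <- 0; hit <- 0
  for (j in k:1) {
    fa <- c(fa, sum(bins[!correct] >= j) / sum(!correct))
    hit <- c(hit, sum(bins[correct] >= j) / sum(correct))
  }
  a <- 0
  for (i in seq_len(length(fa) - 1))
    a <- a + (fa[i + 1] - fa[i]) * (hit[i] + hit[i + 1]) / 2
  a
}

# Trial set with diagnostic confidence (higher when correct), guaranteed
# to contain both classes.
make_trials <- function(n, seed, diagnostic = TRUE) {
  set.seed(seed)
  correct <- c(TRUE, FALSE, runif(n - 2) < 0.7)
  confidence <- if (diagnostic) {
    0.5 + 0.5 * plogis(rnorm(n, ifelse(correct, 1, -0.3), 1.2))
  } else {
    runif(n, 0.5, 1)
  }
  list(correct = correct, confidence = confidence)
}

# A small synthetic cohort shared by several test files, built once.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, spec) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(spec)
  .cohort_cache[[key]]
}
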