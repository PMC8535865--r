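# shared fixtures (built once per test run) and independent oracles

epi_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_epistasis_dataset(epistasis_sim_config(seed = 1))
    cache
  }
})

cohort_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_cohort_dataset(cohort_sim_config(seed = 1))
    cache
  }
})

# published association table: printed 2x2 counts (a = exposed acute,
# b = exposed chronic, c/d = the rest), printed ORs, CIs and p-values
printed_assoc <- data.frame(
  label = c("rs6487213", "rs5417", "rs7658048", "rs12453290", "rs3785157",
            "MARS pair", "MDR triple", "RF-LR pair"),
  a = c(76, 74, 113, 105, 106, 32, 12, 36),
  b = c(20, 19, 18, 19, 18, 14, 6, 10),
  c = c(162, 164, 125, 133, 132, 206, 226, 202),
  d = c(13, 14, 15, 14, 15, 19, 27, 23),
  or = c(3.28, 3.01, 1.33, 1.72, 1.49, 4.74, 4.19, 2.44),
  ci_low = c(1.57, 1.44, 0.64, 0.83, 0.72, 2.14, 1.36, 1.03),
  ci_high = c(7.09, 6.43, 2.79, 3.65, 3.14, 10.39, 11.74, 5.45),
  p = c(0.002, 0.004, 0.448, 0.149, 0.282, 0.001, 0.008, 0.034),
  p_is_upper_bound = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))

# independent Fisher oracle: exhaustive enumeration of all tables with the
# observed margins via factorial arithmetic (no dhyper)
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  lfac <- lgamma(seq_len(n + 1))  # lfac[k+1] = log(k!)
  lp <- function(x) {
    # P(table with top-left = x | margins)
    lfac[r1 + 1] + lfac[r2 + 1] + lfac[c1 + 1] + lfac[n - c1 + 1] -
      lfac[n + 1] - lfac[x + 1] - lfac[r1 - x + 1] - lfac[c1 - x + 1] -
      lfac[r2 - c1 + x + 1]
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(vapply(xs, lp, 0))
  p_obs <- probs[xs == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent naive MDR scorer: literal re-implementation of the per-fold
# labelling and error rules, one cell at a time
naive_mdr_score <- function(data, snp_subset, foldid) {
  g <- data$genotypes[, snp_subset, drop = FALSE]
  y <- data$phenotype
  key <- apply(g, 1, paste, collapse = "|")
  K <- max(foldid)
  tr_err <- te_err <- numeric(K)
  for (f in seq_len(K)) {
    tr <- foldid != f
    thr <- sum(y[tr] == 1) / sum(y[tr] == 0)
    labels <- list()
    for (k in unique(key[tr])) {
      cases <- sum(tr & key == k & y == 1)
      controls <- sum(tr & key == k & y == 0)
      labels[[k]] <- if (controls == 0) (cases > 0) else (cases / controls >= thr)
    }
    pred <- vapply(key, function(k)
      isTRUE(labels[[k]]), TRUE)  # unseen cells -> low risk
    tr_err[f] <- mean(pred[tr] != (y[tr] == 1))
    te_err[f] <- mean(pred[!tr] != (y[!tr] == 1))
  }
  list(train_error = mean(tr_err), test_error = mean(te_err))
}

# small complete-data toy set with one strong pair and noise
toy_dataset <- function(n = 120, seed = 42, n_snps = 5) {
  cfg <- epistasis_sim_config(n_samples = n, n_cases = n / 2, n_snps = n_snps,
                              causal_pair = c(1L, 2L),
                              target_minority_counts = c(round(n * 0.21),
                                                         round(n * 0.23)),
                              seed = seed)
  make_epistasis_dataset(cfg)
}

planted_pair <- c("SNP4", "SNP9")

expect_same_dataset <- function(x, y) {
  expect_identical(x$genotypes, y$genotypes)
  expect_identical(x$phenotype, y$phenotype)
  expect_identical(x$allele_map, y$allele_map)
}
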