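test_that("the GCV formula is computed exactly as written", {
  expect_equal(gcv_score(25, N = 100, k = 3, penalty_p = 3),
               25 / 0.81, tolerance = 1e-12)
  expect_equal(round(gcv_score(25, 100, 3, 3), 3), 30.864)
  expect_equal(gcv_score(0, 50, 4, 2), 0)
  expect_error(gcv_score(10, N = 10, k = 3, penalty_p = 3), "degenerate")
  # strictly increasing in k at fixed RSS and N
  ks <- 0:8
  g <- vapply(ks, function(k) gcv_score(30, 100, k, 3), 0)
  expect_true(all(diff(g) > 0))
})

test_that("an exactly representable indicator signal is fit in one term", {
  set.seed(5)
  g <- matrix(sample(c("AA", "AG", "GG"), 240, replace = TRUE), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(g[, "b"] == "AG")
  d <- genotype_data(g, y)
  fit <- mars_fit(d, pair_scan = FALSE)
  expect_lt(fit$rss, 1e-20)
  expect_identical(fit$k, 1L)
  expect_identical(fit$terms[[1]]$factors[[1]]$snp, "b")
  # either the AG indicator or its complement represents the signal exactly
  expect_true(setequal(fit$terms[[1]]$factors[[1]]$cats, "AG") ||
                setequal(fit$terms[[1]]$factors[[1]]$cats, c("AA", "GG")))
  expect_equal(abs(unname(coef(fit)[2])), 1)
  expect_equal(predict(fit, type = "class"), y)
})

test_that("constant responses and missing data are rejected", {
  g <- matrix(c("AA", "AG", "GG", "AA"), ncol = 1,
              dimnames = list(NULL, "s"))
  expect_error(mars_fit(genotype_data(g, rep(1L, 4))), "binary|constant")
  g12 <- matrix(rep(c("AA", "AG", "GG"), 4), ncol = 1,
                dimnames = list(NULL, "s"))
  expect_error(mars_fit(genotype_data(g12, rep(c(0, 1), 6)),
                        forward_tol = 0), NA)
  expect_error(mars_fit(genotype_data(g, c(0, 0, 1, 1))), "too few")
})

test_that("a high forward tolerance stops the pass on pure noise", {
  # with no candidate explaining >= 10% of the RSS the forward pass should
  # stop immediately on phenotype-independent data in nearly all replicates
  set.seed(31)
  stopped <- vapply(1:25, function(i) {
    d <- make_epistasis_dataset(
      epistasis_sim_config(penetrance = matrix(0.5, 3, 3),
                           seed = sample.int(1e6, 1)))
    fit <- mars_fit(d, forward_tol = 0.10, prune = FALSE)
    fit$forward_k < 13L
  }, TRUE)
  expect_gte(mean(stopped), 0.9)
})

test_that("backward pruning removes a useless term and never worsens GCV", {
  d <- epi_fixture()
  unpruned <- mars_fit(d, prune = FALSE)
  pruned <- mars_prune(unpruned)
  expect_lte(pruned$gcv, unpruned$gcv)
  expect_lte(pruned$k, unpruned$k)
  # the deletion path includes the full model
  expect_equal(pruned$gcv_path[1], unpruned$gcv, tolerance = 1e-9)

  # append a duplicated (hence useless, coefficient-aliased) term
  with_junk <- unpruned
  with_junk$terms <- c(with_junk$terms, with_junk$terms[1])
  with_junk$basis_matrix <- cbind(with_junk$basis_matrix,
                                  with_junk$basis_matrix[, 1])
  with_junk <- dilisnp:::refit_mars(
    lapply(with_junk$terms, function(t) list(factors = t$factors)),
    with_junk$basis_matrix, as.numeric(d$phenotype), d, 3)
  expect_lt(mars_prune(with_junk)$k, with_junk$k)
})

test_that("pruning matches exhaustive best-subset-by-GCV on a small model", {
  d <- toy_dataset(n = 100, seed = 8, n_snps = 6)
  fwd <- mars_fit(d, max_terms = 6, prune = FALSE)
  pruned <- mars_prune(fwd)
  y <- as.numeric(d$phenotype)
  subsets <- unlist(lapply(0:fwd$k, function(m)
    combn(fwd$k, m, simplify = FALSE)), recursive = FALSE)
  gcvs <- vapply(subsets, function(ss) {
    X <- cbind(1, fwd$basis_matrix[, ss, drop = FALSE])
    gcv_score(sum(lm.fit(X, y)$residuals^2), fwd$N, length(ss), fwd$penalty_p)
  }, 0)
  expect_equal(pruned$gcv, min(gcvs), tolerance = 1e-9)
})

test_that("interaction extraction filters by degree and orders by contribution", {
  d <- epi_fixture()
  fit <- mars_fit(d)
  ints <- extract_interactions(fit)
  expect_true(length(ints) >= 1)
  expect_true(all(vapply(ints, function(it) length(it$snps), 0L) >= 2L))
  contribs <- vapply(ints, `[[`, 0, "contribution")
  expect_true(all(diff(contribs) <= 1e-9))
  expect_identical(sort(ints[[1]]$snps), planted_pair)
  # the reported risk cell assigns exactly one category per SNP
  expect_identical(sort(names(ints[[1]]$risk_combination)), planted_pair)
  expect_true(all(nchar(ints[[1]]$risk_combination) == 2L))

  # a purely additive model has no interactions to report
  set.seed(9)
  g <- matrix(sample(c("AA", "AG", "GG"), 300, replace = TRUE), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- as.integer(g[, "a"] == "AA")
  fit2 <- mars_fit(genotype_data(g, y), pair_scan = FALSE, max_degree = 1)
  expect_identical(extract_interactions(fit2), list())
})

test_that("the planted interaction is recovered by the MARS detector across seeds", {
  hits <- sum(vapply(1:40, function(s) {
    d <- make_epistasis_dataset(epistasis_sim_config(seed = 200 + s))
    cand <- mars_detect(d)
    !is.null(cand) && setequal(cand$snps, planted_pair)
  }, TRUE))
  expect_gte(hits, 38)
})

test_that("hinge atoms are available and evaluate correctly", {
  d <- toy_dataset(n = 60, seed = 4, n_snps = 4)
  fit <- mars_fit(d, basis = "both", max_terms = 5)
  expect_s3_class(fit, "snp_mars")
  expect_true(is.finite(fit$gcv))
  # model evaluation on new data agrees with the training fit
  expect_equal(predict(fit, d), predict(fit))
  expect_equal(residuals(fit), as.numeric(d$phenotype) - predict(fit))
})
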