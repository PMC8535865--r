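test_that("cell labelling follows the threshold, tie and empty-cell rules", {
  g <- matrix(c("AA", "AA", "AA", "AA", "AG", "AG", "GG", "GG"), ncol = 1,
              dimnames = list(NULL, "s"))
  y <- c(1, 1, 1, 0, 1, 0, 0, 0)
  d <- genotype_data(g, y)
  cells <- label_cells(d, "s", threshold = 1)
  lab <- setNames(cells$label, cells$s)
  expect_identical(lab[["AA"]], "high")  # 3 cases / 1 control
  expect_identical(lab[["AG"]], "high")  # tie goes to high (>= rule)
  expect_identical(lab[["GG"]], "low")
  # zero controls with at least one case -> high
  d2 <- genotype_data(matrix(c("AA", "AA", "GG", "GG"), ncol = 1,
                             dimnames = list(NULL, "s")), c(1, 1, 0, 0))
  c2 <- label_cells(d2, "s", threshold = 5)
  expect_identical(setNames(c2$label, c2$s)[["AA"]], "high")
  expect_error(label_cells(d, "s", threshold = -1), "positive")
})

test_that("default threshold is the dataset case/control ratio", {
  d <- cohort_fixture()
  cells <- label_cells(d, "rs6487213")
  expect_equal(attr(cells, "threshold"), 33 / 238)
  # CC: 20/76 = 0.263 >= 0.139 -> high; the pooled others are below
  expect_identical(cells$label[cells$rs6487213 == "CC"], "high")
})

test_that("a perfectly separating SNP yields zero train and test error", {
  g <- matrix(rep(c("AA", "GG"), each = 20), ncol = 1,
              dimnames = list(NULL, "s"))
  extra <- matrix(sample(c("CC", "CT"), 80, replace = TRUE), ncol = 2,
                  dimnames = list(NULL, c("n1", "n2")))
  d <- genotype_data(cbind(g, extra), rep(c(1, 0), each = 20))
  ev <- mdr_evaluate(d, "s", n_folds = 5, seed = 1)
  expect_equal(ev$train_error, 0)
  expect_equal(ev$test_error, 0)
  fit <- mdr_fit(d, max_order = 2, n_folds = 5, seed = 1)
  expect_identical(fit$final$snp_subset, "s")
})

test_that("vectorised evaluation agrees with the naive per-cell re-scorer", {
  for (seed in 1:4) {
    d <- toy_dataset(n = 80, seed = seed, n_snps = 5)
    foldid <- dilisnp:::stratified_folds(d$phenotype, 5, seed)
    subsets <- list("SNP1", c("SNP1", "SNP2"), c("SNP3", "SNP5"),
                    c("SNP1", "SNP2", "SNP4"))
    for (ss in subsets) {
      fast <- mdr_evaluate(d, ss, foldid = foldid)
      slow <- naive_mdr_score(d, ss, foldid)
      expect_equal(fast$train_error, slow$train_error, tolerance = 1e-12)
      expect_equal(fast$test_error, slow$test_error, tolerance = 1e-12)
    }
  }
})

test_that("search selection equals a brute-force re-scorer on a toy dataset", {
  d <- toy_dataset(n = 80, seed = 5, n_snps = 5)
  foldid <- dilisnp:::stratified_folds(d$phenotype, 10, 5)
  fit <- mdr_fit(d, max_order = 2, n_folds = 10, seed = 5)
  # brute force over all orders and subsets with the naive scorer
  best_by_order <- lapply(1:2, function(ord) {
    subs <- combn(d$snp_ids, ord, simplify = FALSE)
    scores <- vapply(subs, function(ss)
      naive_mdr_score(d, ss, foldid)$train_error, 0)
    list(snps = subs[[which.min(scores)]],
         train = min(scores),
         test = naive_mdr_score(d, subs[[which.min(scores)]],
                                foldid)$test_error)
  })
  for (ord in 1:2) {
    expect_identical(fit$per_order[[ord]]$snp_subset,
                     best_by_order[[ord]]$snps)
    expect_equal(fit$per_order[[ord]]$train_error,
                 best_by_order[[ord]]$train)
  }
  naive_final <- best_by_order[[which.min(vapply(best_by_order, `[[`, 0,
                                                 "test"))]]
  expect_identical(sort(fit$final$snp_subset), sort(naive_final$snps))
})

test_that("shuffled phenotypes give chance-level test error", {
  set.seed(21)
  errs <- replicate(30, {
    d <- epi_fixture()
    d_null <- genotype_data(d$genotypes, sample(d$phenotype))
    mdr_evaluate(d_null, planted_pair, n_folds = 10,
                 seed = sample.int(1e6, 1))$test_error
  })
  expect_equal(mean(errs), 0.5, tolerance = 0.03)
})

test_that("the planted pair beats every other pair on the fixture", {
  d <- epi_fixture()
  foldid <- dilisnp:::stratified_folds(d$phenotype, 10, 1)
  pairs <- combn(d$snp_ids, 2, simplify = FALSE)
  errs <- vapply(pairs, function(p)
    mdr_evaluate(d, p, foldid = foldid)$test_error, 0)
  planted <- which(vapply(pairs, function(p)
    setequal(p, planted_pair), TRUE))
  expect_identical(which.min(errs), planted)
  expect_true(all(errs[-planted] > errs[planted]))
})

test_that("search is deterministic and internally consistent", {
  d <- epi_fixture()
  f1 <- mdr_fit(d, max_order = 2, seed = 3)
  f2 <- mdr_fit(d, max_order = 2, seed = 3)
  expect_identical(f1$per_order, f2$per_order)
  # the final model minimises test error among per-order winners
  expect_equal(f1$final$test_error,
               min(vapply(f1$per_order, `[[`, 0, "test_error")))
  expect_true(all(vapply(f1$per_order, `[[`, 0L, "cv_consistency") <= 10L))
})

test_that("order-1 MDR agrees with the marginal genotype-grouping classifier", {
  d <- cohort_fixture()
  cells <- label_cells(d, "rs6487213")
  high <- cells$rs6487213[cells$label == "high"]
  tab <- build_table(d, list(rs6487213 = high))
  pred_err <- (tab$a + tab$d) / 271  # exposed controls + unexposed cases
  full_fit <- label_cells(d, "rs6487213")
  miscl <- sum(ifelse(full_fit$label == "high", full_fit$controls,
                      full_fit$cases)) / 271
  expect_equal(miscl, pred_err)
})

test_that("the planted pair is recovered across generator seeds", {
  hits <- sum(vapply(1:100, function(s) {
    d <- make_epistasis_dataset(epistasis_sim_config(seed = s))
    identical(sort(mdr_fit(d, max_order = 2, seed = s)$final$snp_subset),
              planted_pair)
  }, TRUE))
  expect_gte(hits, 95)
})

test_that("budget and stratification guards trigger", {
  d <- epi_fixture()
  expect_error(mdr_fit(d, max_order = 3, budget = 100), "budget")
  tiny <- genotype_data(matrix(c("AA", "AG", "GG", "AA"), ncol = 1,
                               dimnames = list(NULL, "s")), c(1, 0, 0, 0))
  expect_error(mdr_fit(tiny, max_order = 1, n_folds = 4), "single-class")
  expect_error(mdr_fit(d, max_order = 0), "max_order")
})

test_that("prediction maps unseen cells to low risk", {
  d <- toy_dataset(n = 80, seed = 2, n_snps = 4)
  fit <- mdr_fit(d, max_order = 2, seed = 2)
  pred <- predict(fit, d)
  expect_true(all(pred %in% 0:1))
  # a fabricated genotype combination never seen in training -> 0
  g <- d$genotypes[1:2, , drop = FALSE]
  g[, fit$final$snp_subset] <- "TT"
  unseen <- suppressWarnings(genotype_data(g, c(0L, 0L),
                                           allele_map = d$allele_map))
  if (!any(apply(d$genotypes[, fit$final$snp_subset, drop = FALSE], 1,
                 function(r) all(r == "TT"))))
    expect_identical(predict(fit, unseen), c(0L, 0L))
})
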