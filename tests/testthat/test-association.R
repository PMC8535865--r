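test_that("all eight published odds ratios are reproduced to 2 d.p.", {
  for (i in seq_len(nrow(printed_assoc))) {
    r <- printed_assoc[i, ]
    tab <- contingency_2x2(r$a, r$b, r$c, r$d, r$label)
    expect_equal(round(as.numeric(odds_ratio(tab)), 2), r$or,
                 info = r$label)
  }
})

test_that("published p-values match the Wald log-OR test at printed precision", {
  # the published table's p-values follow the logistic-regression Wald test
  # (verified against all eight rows), not the Fisher exact test
  for (i in seq_len(nrow(printed_assoc))) {
    r <- printed_assoc[i, ]
    p <- wald_p_value(contingency_2x2(r$a, r$b, r$c, r$d))
    if (r$p_is_upper_bound) expect_lt(p, r$p)
    else expect_equal(round(p, 3), r$p, info = r$label)
  }
})

test_that("published confidence intervals match the profile-likelihood method", {
  for (i in seq_len(nrow(printed_assoc))) {
    r <- printed_assoc[i, ]
    ci <- or_confidence_interval(contingency_2x2(r$a, r$b, r$c, r$d),
                                 method = "profile")
    expect_equal(round(ci, 2), c(r$ci_low, r$ci_high), info = r$label)
  }
})

test_that("Fisher p equals exhaustive margin-preserving enumeration", {
  # spot values first: the 11-table enumeration for (1,9,9,1)
  expect_equal(fisher_exact_two_sided(contingency_2x2(1, 9, 9, 1)),
               fisher_oracle(1, 9, 9, 1), tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(contingency_2x2(76, 20, 162, 13)),
               fisher_oracle(76, 20, 162, 13), tolerance = 1e-12)
  # a symmetric table with equal margins is the most probable one
  expect_equal(fisher_exact_two_sided(contingency_2x2(10, 10, 10, 10)), 1)
  # random property sweep at small N (the exhaustive N<=40 sweep runs in
  # the acceptance suite)
  set.seed(7)
  for (rep in 1:200) {
    k <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    if (sum(k) == 0) next
    tab <- try(contingency_2x2(k[1], k[2], k[3], k[4]), silent = TRUE)
    if (inherits(tab, "try-error")) next
    expect_equal(fisher_exact_two_sided(tab),
                 fisher_oracle(k[1], k[2], k[3], k[4]), tolerance = 1e-9)
  }
})

test_that("odds ratio symmetries hold", {
  set.seed(3)
  for (rep in 1:20) {
    k <- 1 + as.integer(rmultinom(1, 40, rep(0.25, 4)))
    or <- as.numeric(odds_ratio(contingency_2x2(k[1], k[2], k[3], k[4])))
    # swapping exposure rows gives the reciprocal
    expect_equal(as.numeric(odds_ratio(contingency_2x2(k[3], k[4],
                                                       k[1], k[2]))), 1 / or)
    # swapping rows AND columns leaves the OR unchanged
    expect_equal(as.numeric(odds_ratio(contingency_2x2(k[4], k[3],
                                                       k[2], k[1]))), or)
  }
  expect_equal(as.numeric(odds_ratio(contingency_2x2(10, 10, 10, 10))), 1)
})

test_that("zero cells trigger the flagged Haldane correction", {
  tab <- contingency_2x2(5, 0, 7, 3)
  or <- odds_ratio(tab)
  expect_true(attr(or, "haldane"))
  expect_equal(as.numeric(or), (0.5 * 7.5) / (5.5 * 3.5))
  expect_error(odds_ratio(contingency_2x2(0, 0, 0, 0)), "total")
  ci <- or_confidence_interval(tab, method = "wald")
  expect_true(attr(ci, "haldane"))
})

test_that("confidence intervals bracket the estimate and widen with the level", {
  set.seed(11)
  for (rep in 1:20) {
    k <- 1 + as.integer(rmultinom(1, 60, rep(0.25, 4)))
    tab <- contingency_2x2(k[1], k[2], k[3], k[4])
    or <- as.numeric(odds_ratio(tab))
    for (m in c("wald", "profile", "exact-conditional")) {
      ci90 <- or_confidence_interval(tab, method = m, level = 0.90)
      ci99 <- or_confidence_interval(tab, method = m, level = 0.99)
      if (m == "wald") {
        expect_lte(ci90[1], or); expect_gte(ci90[2], or)
      }
      expect_lte(ci99[1], ci90[1])
      expect_gte(ci99[2], ci90[2])
    }
  }
  expect_error(or_confidence_interval(contingency_2x2(1, 2, 3, 4), level = 1.2),
               "level")
})

test_that("the Wald interval matches its closed form", {
  tab <- contingency_2x2(76, 20, 162, 13)
  k <- c(76, 20, 162, 13)
  expected <- exp(log((20 * 162) / (76 * 13)) +
                    c(-1, 1) * qnorm(0.975) * sqrt(sum(1 / k)))
  expect_equal(as.numeric(or_confidence_interval(tab, "wald")), expected)
})

test_that("build_table applies the all-of rule over multilocus groupings", {
  d <- cohort_fixture()
  # grouping over zero SNPs: everyone exposed
  tab0 <- build_table(d, list())
  expect_identical(c(tab0$c, tab0$d), c(0L, 0L))
  expect_identical(tab0$a + tab0$b, 271L)
  # unknown SNPs and malformed categories error
  expect_error(build_table(d, list(nope = "CC")), "unknown SNP")
  expect_error(build_table(d, list(rs5417 = "ZZ")), "invalid genotype")
  # grouping specifications are canonicalised ("TC" == "CT")
  t1 <- build_table(d, list(rs3785157 = "TC"))
  t2 <- build_table(d, list(rs3785157 = "CT"))
  expect_identical(c(t1$a, t1$b), c(t2$a, t2$b))
  # counts partition the cohort
  t3 <- build_table(d, list(rs5417 = "AA", rs3785157 = "CC"))
  expect_identical(t3$a + t3$b + t3$c + t3$d, 271L)
  expect_identical(c(t3$a, t3$b), c(36L, 10L))
})

test_that("snp_association assembles a coherent record", {
  res <- snp_association(table = contingency_2x2(76, 20, 162, 13,
                                                 "rs6487213=CC"))
  expect_s3_class(res, "assoc_result")
  expect_equal(round(res$odds_ratio, 2), 3.28)
  expect_lte(res$ci_low, res$ci_high)
  expect_true(res$p_fisher >= 0 && res$p_fisher <= 1)
  expect_output(print(res), "rs6487213")
})
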