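test_that("Welch t from summaries matches the raw-data test and its limits", {
  set.seed(11)
  x <- rnorm(16, 68, 7.5); y <- rnorm(16, 76, 7.9)
  ours <- welch_t_test(x, y)
  ref <- t.test(y, x) # Welch by default; (mean2 - mean1) orientation
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)

  # identical summaries: t = 0, p = 1
  s <- two_sample_summary(8, 8, 5, 5, 2, 2)
  expect_equal(welch_t_test(s), list(t = 0, df = 14, p = 1),
               tolerance = 1e-12)

  # equal n and equal variances: reduces to the pooled Student t on 2n-2 df
  s2 <- two_sample_summary(10, 10, 1, 2.3, 1.7, 1.7)
  w <- welch_t_test(s2)
  t_pooled <- (2.3 - 1) / sqrt(1.7 * (1 / 10 + 1 / 10))
  expect_equal(w$t, t_pooled, tolerance = 1e-12)
  expect_equal(w$df, 18, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_pooled), 18), tolerance = 1e-12)

  # degenerate zero-variance conventions
  expect_equal(welch_t_test(two_sample_summary(4, 4, 1, 1, 0, 0))$p, 1)
  expect_warning(z <- welch_t_test(two_sample_summary(4, 4, 1, 2, 0, 0)))
  expect_equal(z$p, 0)
})

test_that("Fisher exact enumeration matches stats::fisher.test on random tables", {
  set.seed(42)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(tab),
                 fisher.test(tab)$p.value, tolerance = 1e-12,
                 info = paste(tab, collapse = ","))
  }
  expect_equal(fisher_exact_2x2(matrix(c(1, 9, 11, 3), 2, byrow = TRUE)),
               fisher.test(matrix(c(1, 9, 11, 3), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
})

test_that("Fisher exact: symmetry, invariances, degenerate margins", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2)), 1)
  tab <- matrix(c(2, 7, 8, 1), 2)
  p0 <- fisher_exact_2x2(tab)
  expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p0, tolerance = 1e-14)
  expect_equal(fisher_exact_2x2(t(tab)), p0, tolerance = 1e-14)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)), 1)
})

test_that("Pearson chi-squared matches the closed form and stats::chisq.test", {
  # N (ad - bc)^2 / (r1 r2 c1 c2) on the sex table
  tab <- matrix(c(10, 6, 7, 9), 2, byrow = TRUE)
  res <- pearson_chi2_2x2(tab)
  expect_equal(res$chi2, 32 * (10 * 9 - 6 * 7)^2 / (16 * 16 * 17 * 15),
               tolerance = 1e-12)
  expect_equal(res$chi2, unname(chisq.test(tab, correct = FALSE)$statistic),
               tolerance = 1e-12)
  expect_equal(pearson_chi2_2x2(tab, yates = TRUE)$p,
               unname(chisq.test(tab)$p.value), tolerance = 1e-12)
  # proportional rows: no association
  prop <- matrix(c(10, 20, 5, 10), 2, byrow = TRUE)
  expect_equal(pearson_chi2_2x2(prop)$chi2, 0, tolerance = 1e-12)
  expect_equal(pearson_chi2_2x2(prop)$p, 1)
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)),
               "expected count")
})

test_that("BH step-up adjustment: hand example, properties, p.adjust oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-15)) # order-preserving on sorted p
  }
  expect_equal(bh_adjust(c(0.1, NA, 0.5))[2], NA_real_)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Shannon index: closed forms, maximum-entropy property, vegan oracle", {
  expect_equal(shannon_index(rep(0.25, 4)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 0, 0)), 0)
  expect_equal(shannon_index(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)
  expect_equal(round(shannon_index(c(0.5, 0.25, 0.25)), 4), 1.0397)
  set.seed(9)
  for (i in 1:10) {
    p <- rgamma(6, 1); p <- p / sum(p)
    expect_lte(shannon_index(p), log(6) + 1e-12)
    expect_equal(shannon_index(p), unname(vegan::diversity(rbind(p))),
                 tolerance = 1e-12)
  }
  expect_error(shannon_index(c(0, 0)), "all-zero")
})
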