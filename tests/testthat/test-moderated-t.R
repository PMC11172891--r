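test_that("with d0 = 0 the moderated t reduces to the ordinary pooled t", {
  sim <- simulate_proteome(proteome_sim_config(n_proteins = 30,
                                               censor_midpoint = -1e3,
                                               censor_slope = 1e3, seed = 9))
  X <- sim$table$intensities
  fit <- fit_moderated_t(X, sim$annotation, d0 = 0, s0sq = 1)
  grp <- sim$annotation$group == "patient"
  for (i in c(1, 7, 30)) {
    ref <- t.test(X[i, grp], X[i, !grp], var.equal = TRUE)
    expect_equal(unname(fit$t_mod[i]), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(unname(fit$p_raw[i]), ref$p.value, tolerance = 1e-10)
  }
  expect_equal(fit$df_total, 30)
})

test_that("posterior variance follows the shrinkage formula; d0 -> Inf equalises scales", {
  # hand case: d0 = 4, s0^2 = 1, d = 2, s^2 = 2 -> posterior 8/6
  X <- rbind(p1 = c(1, 3, 11, 13)) # within-group variances 2 and 2 -> s^2 = 2
  colnames(X) <- c("A1", "A2", "B1", "B2")
  ann <- sample_annotation(colnames(X), rep(c("patient", "control"), each = 2))
  fit <- fit_moderated_t(X, ann, d0 = 4, s0sq = 1)
  expect_equal(unname(fit$s2), 2, tolerance = 1e-12)
  se_expected <- sqrt((4 * 1 + 2 * 2) / 6 * (1 / 2 + 1 / 2))
  expect_equal(unname(fit$t_mod), (2 - 12) / se_expected, tolerance = 1e-12)
  expect_equal(fit$df_total, 6)

  # d0 = Inf: every protein tested at the common prior variance
  sim <- simulate_proteome(proteome_sim_config(n_proteins = 40,
                                               censor_midpoint = -1e3,
                                               censor_slope = 1e3, seed = 2))
  finf <- fit_moderated_t(sim$table$intensities, sim$annotation,
                          d0 = Inf, s0sq = 0.3)
  z <- finf$t_mod / finf$log2fc
  expect_equal(max(abs(z)) / min(abs(z)), 1, tolerance = 1e-12)
  expect_true(is.infinite(finf$df_total))
})

test_that("hyperparameter estimation recovers a known variance prior", {
  cfg <- proteome_sim_config(n_proteins = 3000, frac_differential = 0,
                             d0_true = 4, s0sq_true = 1,
                             censor_midpoint = -1e3, censor_slope = 1e3,
                             seed = 13)
  sim <- simulate_proteome(cfg)
  fit <- fit_moderated_t(sim$table$intensities, sim$annotation)
  expect_gt(fit$d0_hat, 2.5)
  expect_lt(fit$d0_hat, 6.5)
  expect_lt(abs(fit$s0sq_hat - 1), 0.15)
})

test_that("moderated statistics agree with the limma empirical-Bayes fit", {
  sim <- simulate_proteome(proteome_sim_config(n_proteins = 1500,
                                               censor_midpoint = -1e3,
                                               censor_slope = 1e3, seed = 3))
  X <- sim$table$intensities
  ann <- sim$annotation
  fit <- fit_moderated_t(X, ann)

  design <- cbind(1, as.numeric(ann$group == "patient"))
  lf <- limma::eBayes(limma::lmFit(X, design))
  expect_equal(unname(fit$log2fc), unname(lf$coefficients[, 2]),
               tolerance = 1e-10)
  # hyperparameter estimators differ in bias correction; close, not identical
  expect_lt(abs(fit$d0_hat - lf$df.prior) / lf$df.prior, 0.25)
  expect_lt(abs(fit$s0sq_hat - lf$s2.prior) / lf$s2.prior, 0.1)
  expect_gt(cor(fit$t_mod, lf$t[, 2]), 0.999)
})

test_that("degenerate and incomplete inputs are rejected", {
  ann <- tiny_annotation()
  Xna <- matrix(c(NA, rnorm(8 * 3 - 1)), 3, 8,
                dimnames = list(NULL, ann$sample_id))
  expect_error(fit_moderated_t(Xna, ann), "complete")
  X0 <- matrix(5, 3, 8, dimnames = list(NULL, ann$sample_id))
  expect_error(fit_moderated_t(X0, ann), "zero")
})

test_that("trigamma inverse matches uniroot on a grid", {
  for (y in c(1e-4, 0.01, 0.3, 1, 5, 100)) {
    x <- tearosm:::trigamma_inverse(y)
    expect_equal(trigamma(x), y, tolerance = 1e-8)
  }
  expect_true(is.infinite(tearosm:::trigamma_inverse(0)))
})
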