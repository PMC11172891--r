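test_that("proteome simulator: null config, censoring limits, determinism", {
  cfg0 <- proteome_sim_config(n_proteins = 100, frac_differential = 0, seed = 2)
  s0 <- simulate_proteome(cfg0)
  expect_true(all(s0$truth$true_log2fc == 0))
  expect_true(all(!s0$truth$is_differential))

  # steep censoring far below the data: no missing values
  cfg_nc <- proteome_sim_config(n_proteins = 100, censor_midpoint = -1e3,
                                censor_slope = 1e3, seed = 2)
  expect_equal(sum(simulate_proteome(cfg_nc)$table$missing_mask), 0)

  # bit-identical outputs for identical config + seed
  s1 <- simulate_proteome(proteome_sim_config(n_proteins = 200, seed = 5))
  s2 <- simulate_proteome(proteome_sim_config(n_proteins = 200, seed = 5))
  expect_identical(s1$table$intensities, s2$table$intensities)
  expect_identical(s1$truth$true_log2fc, s2$truth$true_log2fc)
  expect_identical(s1$annotation, s2$annotation)

  # cohort structure: 16/16 with the 7/9 vs 10/6 sex split
  ann <- s1$annotation
  expect_equal(unname(table(ann$group)), c(16, 16), ignore_attr = TRUE)
  expect_equal(sum(ann$sex == "female" & ann$group == "patient"), 7)
  expect_equal(sum(ann$sex == "female" & ann$group == "control"), 10)

  expect_error(proteome_sim_config(censor_slope = 0), "censor_slope")
  expect_error(proteome_sim_config(frac_differential = 1.2), "frac_differential")
  expect_error(proteome_sim_config(effect_size_sd = NaN), "effect_size_sd")
})

test_that("observed group-mean differences regress on the true effects with slope 1", {
  s <- simulate_proteome(proteome_sim_config(seed = 4))
  grp <- s$annotation$group == "patient"
  X <- s$table$intensities
  diff_obs <- rowMeans(X[, grp], na.rm = TRUE) - rowMeans(X[, !grp], na.rm = TRUE)
  slope <- coef(lm(diff_obs ~ s$truth$true_log2fc))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)
})

test_that("logistic left-censoring follows its closed form and is monotone", {
  # empirical missing rate at fixed intensity vs the logistic formula
  n <- 1e5
  X <- matrix(2, n, 1) # x = midpoint + ln(3), slope 1 -> p = 0.25
  m <- censor_mnar(X, midpoint = 2 - log(3), slope = 1, seed = 8)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(m) - 0.25), 3 * se)

  # x = midpoint -> 0.5
  m2 <- censor_mnar(matrix(5, n, 1), midpoint = 5, slope = 2, seed = 9)
  expect_lt(abs(mean(m2) - 0.5), 3 * sqrt(0.25 / n))

  # monotonicity: missing fraction non-increasing across intensity bins
  x <- matrix(seq(10, 30, length.out = 2e4), ncol = 1)
  mm <- censor_mnar(x, midpoint = 20, slope = 0.8, seed = 10)
  bins <- cut(x, breaks = 10)
  frac <- tapply(mm, bins, mean)
  expect_true(all(diff(frac) <= 3 * sqrt(0.25 / table(bins)[-1]) + 1e-12))
  expect_error(censor_mnar(x, 20, slope = -1), "slope")
})

test_that("microbiome simulator: closure, marker prevalence, determinism", {
  s <- simulate_microbiome(microbiome_sim_config(seed = 3))
  expect_true(all(abs(colSums(s$table$abundances) - 1) < 1e-12))

  # marker absent everywhere at zero prevalence
  s0 <- simulate_microbiome(
    microbiome_sim_config(marker_taxon_prevalence = c(0, 0), seed = 3))
  mk <- grep("mastitidis", rownames(s0$table$abundances))
  expect_true(all(s0$table$abundances[mk, ] == 0))

  # single taxon: composition closure forces abundance 1
  one <- data.frame(lineage = "k__Bacteria|p__Firmicutes|g__X|s__X_y",
                    concentration = 2)
  s1 <- simulate_microbiome(
    microbiome_sim_config(taxa = one, marker_taxon = NULL, seed = 1))
  expect_true(all(s1$table$abundances == 1))

  # binomial expectation of positive counts at prevalence (0, 7/16)
  pos <- sapply(1:30, function(sd) {
    sim <- simulate_microbiome(microbiome_sim_config(seed = sd))
    grp <- sim$annotation$group
    mk <- grep("mastitidis", rownames(sim$table$abundances))
    c(sum(sim$table$abundances[mk, grp == "patient"] > 0),
      sum(sim$table$abundances[mk, grp == "control"] > 0))
  })
  expect_equal(mean(pos[1, ]), 0)
  se <- sqrt(16 * (7 / 16) * (9 / 16) / 30)
  expect_lt(abs(mean(pos[2, ]) - 7), 3 * se)

  s2 <- simulate_microbiome(microbiome_sim_config(seed = 3))
  expect_identical(s$table$abundances, s2$table$abundances)
})

test_that("sub-seed splitting is deterministic and decorrelates streams", {
  expect_identical(split_seed(42, 1), split_seed(42, 1))
  expect_false(split_seed(42, 1) == split_seed(42, 2))
  expect_false(split_seed(42, 1) == split_seed(43, 1))
  s <- vapply(0:100, function(k) split_seed(7, k), integer(1))
  expect_true(all(s >= 0 & s < 2^31 - 1))
})
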