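# Synthetic label-free proteome generator. Emulates a two-group tear-fluid
# cohort: per-protein log2 baselines, group effects for a fraction of
# proteins, scaled-inverse-chi-squared within-protein variances (so the
# empirical-Bayes variance moderation can be validated by parameter
# recovery), and intensity-dependent (left-censored) missingness.

#' Configuration for the synthetic proteome generator
#'
#' Defaults mirror a 32-sample tear-proteomics cohort: 16 patients (7 female /
#' 9 male) versus 16 controls (10 female / 6 male), about 2250 protein groups,
#' and a differential fraction of roughly 5.5% (123/2250). Intensities are in
#' log2 units throughout.
#'
#' @param n_proteins Number of protein groups.
#' @param n_per_group Integer pair: samples in (patients, controls).
#' @param sex_counts List with elements `patients` and `controls`, each an
#'   integer pair (female, male) summing to the group size.
#' @param frac_differential Fraction of proteins with a true group effect.
#' @param effect_size_sd SD (log2 units) of true effects among differential
#'   proteins; effects are drawn Normal(0, effect_size_sd^2).
#' @param baseline_mean,baseline_sd_between_proteins Mean and SD (log2) of
#'   per-protein baseline abundances.
#' @param d0_true,s0sq_true Within-protein variances are drawn
#'   scaled-inverse-chi-squared with df `d0_true` and scale `s0sq_true`.
#' @param censor_midpoint Log2 intensity at which a cell is missing with
#'   probability 0.5.
#' @param censor_slope Steepness (1/log2 units) of the logistic missingness
#'   curve; larger = sharper detection limit. Must be > 0.
#' @param frac_single_peptide Fraction of proteins assigned a single
#'   identified peptide (to exercise the peptide-count filter).
#' @param frac_contaminant Fraction flagged as contaminants.
#' @param mean_ages,sd_ages Numeric pairs (patients, controls) for simulated
#'   ages in years.
#' @param output_scale `"log2"` or `"raw"` (`2^x`) intensities in the output
#'   table.
#' @param seed Integer seed.
#' @return List of class `proteome_sim_config`.
#' @export
proteome_sim_config <- function(n_proteins = 2250,
                                n_per_group = c(16, 16),
                                sex_counts = list(patients = c(7, 9),
                                                  controls = c(10, 6)),
                                frac_differential = 123 / 2250,
                                effect_size_sd = 1.5,
                                baseline_mean = 20,
                                baseline_sd_between_proteins = 2.5,
                                d0_true = 4,
                                s0sq_true = 0.25,
                                censor_midpoint = 16,
                                censor_slope = 0.8,
                                frac_single_peptide = 0.05,
                                frac_contaminant = 0.02,
                                mean_ages = c(76.5, 68.1),
                                sd_ages = c(7.7, 7.3),
                                output_scale = c("log2", "raw"),
                                seed = 1) {
  check_scalar(n_proteins, "n_proteins", lower = 1, integer = TRUE)
  stopifnot(length(n_per_group) == 2)
  check_scalar(n_per_group[1], "n_per_group[1]", lower = 1, integer = TRUE)
  check_scalar(n_per_group[2], "n_per_group[2]", lower = 1, integer = TRUE)
  for (g in c("patients", "controls")) {
    sc <- sex_counts[[g]]
    if (is.null(sc) || length(sc) != 2 || any(sc < 0))
      stop("config field 'sex_counts$", g, "' must be a (female, male) pair")
  }
  if (sum(sex_counts$patients) != n_per_group[1] ||
      sum(sex_counts$controls) != n_per_group[2])
    stop("config field 'sex_counts' must sum to the group sizes")
  check_scalar(frac_differential, "frac_differential", lower = 0, upper = 1)
  check_scalar(effect_size_sd, "effect_size_sd", lower = 0)
  check_scalar(baseline_mean, "baseline_mean")
  check_scalar(baseline_sd_between_proteins, "baseline_sd_between_proteins",
               lower = 0)
  check_scalar(d0_true, "d0_true", lower = 0, strict_lower = TRUE)
  check_scalar(s0sq_true, "s0sq_true", lower = 0, strict_lower = TRUE)
  check_scalar(censor_midpoint, "censor_midpoint")
  check_scalar(censor_slope, "censor_slope", lower = 0, strict_lower = TRUE)
  check_scalar(frac_single_peptide, "frac_single_peptide", lower = 0, upper = 1)
  check_scalar(frac_contaminant, "frac_contaminant", lower = 0, upper = 1)
  check_scalar(seed, "seed", integer = TRUE)
  structure(as.list(environment()), class = "proteome_sim_config")
}

#' Left-censoring (missing-not-at-random) mask
#'
#' Each cell is set missing independently with probability
#' `1 / (1 + exp(slope * (x - midpoint)))`: the probability is 0.5 at the
#' midpoint and rises monotonically as the intensity falls below it, emulating
#' a soft detection limit.
#'
#' @param intensities Numeric matrix of log2 intensities.
#' @param midpoint Log2 intensity of 50% missingness.
#' @param slope Logistic steepness, > 0.
#' @param seed Integer seed.
#' @return Logical matrix; `TRUE` marks cells to censor.
#' @export
censor_mnar <- function(intensities, midpoint, slope, seed = 1) {
  check_scalar(midpoint, "midpoint")
  check_scalar(slope, "slope", lower = 0, strict_lower = TRUE)
  x <- as.matrix(intensities)
  p_miss <- 1 / (1 + exp(slope * (x - midpoint)))
  with_seed(seed, {
    mask <- matrix(stats::runif(length(x)) < p_miss, nrow(x), ncol(x))
    dimnames(mask) <- dimnames(x)
    mask
  })
}

#' Simulate a two-group label-free proteome with ground truth
#'
#' Generates complete log2 intensities
#' `X[g, s] = baseline_g + effect_g * I(s is patient) + eps`,
#' `eps ~ Normal(0, sigma2_g)` with `sigma2_g` drawn scaled-inverse-chi-squared
#' `(d0_true, s0sq_true)`, then applies logistic left-censoring
#' ([censor_mnar()]) and attaches peptide counts and contaminant flags.
#'
#' @param config A [proteome_sim_config()].
#' @return List with `table` ([protein_groups()]), `annotation`
#'   ([sample_annotation()]), and `truth` (class `sim_truth`: per-protein
#'   `is_differential`, `true_log2fc`, `true_within_variance`, censor
#'   parameters, and the complete pre-censoring matrix `complete_log2`).
#' @export
simulate_proteome <- function(config = proteome_sim_config()) {
  stopifnot(inherits(config, "proteome_sim_config"))
  cfg <- config
  n_pat <- cfg$n_per_group[1]; n_ctl <- cfg$n_per_group[2]
  n_s <- n_pat + n_ctl
  n_p <- cfg$n_proteins
  sample_id <- c(sprintf("PAT%02d", seq_len(n_pat)),
                 sprintf("CTL%02d", seq_len(n_ctl)))
  group <- factor(rep(c("patient", "control"), c(n_pat, n_ctl)),
                  levels = c("patient", "control"))
  sex <- factor(c(rep(c("female", "male"), cfg$sex_counts$patients),
                  rep(c("female", "male"), cfg$sex_counts$controls)),
                levels = c("female", "male"))

  gen <- with_seed(split_seed(cfg$seed, 1L), {
    age <- round(c(stats::rnorm(n_pat, cfg$mean_ages[1], cfg$sd_ages[1]),
                   stats::rnorm(n_ctl, cfg$mean_ages[2], cfg$sd_ages[2])))
    baseline <- stats::rnorm(n_p, cfg$baseline_mean,
                             cfg$baseline_sd_between_proteins)
    is_diff <- stats::runif(n_p) < cfg$frac_differential
    effect <- ifelse(is_diff, stats::rnorm(n_p, 0, cfg$effect_size_sd), 0)
    # scaled-inverse-chi-squared(d0, s0^2) = d0 * s0^2 / chisq(d0)
    sigma2 <- cfg$d0_true * cfg$s0sq_true / stats::rchisq(n_p, cfg$d0_true)
    mu <- outer(baseline, rep(1, n_s)) +
      outer(effect, as.numeric(group == "patient"))
    X <- mu + matrix(stats::rnorm(n_p * n_s), n_p, n_s) * sqrt(sigma2)
    pep <- ifelse(stats::runif(n_p) < cfg$frac_single_peptide, 1L,
                  2L + stats::rpois(n_p, 8))
    contam <- stats::runif(n_p) < cfg$frac_contaminant
    list(age = age, is_diff = is_diff, effect = effect, sigma2 = sigma2,
         X = X, pep = pep, contam = contam)
  })

  dimnames(gen$X) <- list(sprintf("P%05d", seq_len(n_p)), sample_id)
  mask <- censor_mnar(gen$X, cfg$censor_midpoint, cfg$censor_slope,
                      seed = split_seed(cfg$seed, 2L))
  observed <- gen$X
  observed[mask] <- NA_real_
  scale <- match.arg(cfg$output_scale, c("log2", "raw"))
  if (scale == "raw") observed <- 2^observed

  table <- protein_groups(observed, peptide_counts = gen$pep,
                          contaminant_flag = gen$contam, scale = scale)
  ann <- sample_annotation(sample_id, group, sex, gen$age)
  truth <- structure(list(
    is_differential = gen$is_diff,
    true_log2fc = gen$effect,
    true_within_variance = gen$sigma2,
    censor_params = c(midpoint = cfg$censor_midpoint, slope = cfg$censor_slope),
    complete_log2 = gen$X
  ), class = "sim_truth")
  list(table = table, annotation = ann, truth = truth)
}
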