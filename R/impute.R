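#' Imputation configuration
#'
#' Downshifted-Gaussian imputation of left-censored intensities: missing
#' cells in sample `s` are drawn from
#' `Normal(mu_s - downshift_factor * sigma_s, (width_factor * sigma_s)^2)`,
#' where `mu_s` and `sigma_s` are the mean and SD of the observed log2
#' intensities in that sample. Defaults (width 0.3, downshift 2.5, 20
#' cycles) are the standard proteomics choices.
#'
#' @param width_factor Width of the imputation distribution as a multiple of
#'   the per-sample SD (default 0.3).
#' @param downshift_factor Downshift of its centre in per-sample SDs
#'   (default 2.5).
#' @param n_cycles Number of independent imputation cycles used for
#'   stability flagging (default 20).
#' @return List of class `imputation_config`.
#' @export
imputation_config <- function(width_factor = 0.3, downshift_factor = 2.5,
                              n_cycles = 20) {
  check_scalar(width_factor, "width_factor", lower = 0, strict_lower = TRUE)
  check_scalar(downshift_factor, "downshift_factor")
  check_scalar(n_cycles, "n_cycles", lower = 1, integer = TRUE)
  structure(as.list(environment()), class = "imputation_config")
}

#' Impute missing log2 intensities by per-sample downshifted Gaussians
#'
#' Observed cells are never modified; each missing cell draws independently
#' from the sample's downshifted Gaussian. Deterministic given `cycle_seed`.
#'
#' @param t A [protein_groups()] on the `"log2"` scale, each sample with at
#'   least 2 observed values.
#' @param cfg An [imputation_config()].
#' @param cycle_seed Integer seed for this imputation cycle.
#' @return Complete numeric matrix of log2 intensities (same dimnames as the
#'   input), with attribute `"imputed_mask"` marking the filled cells.
#' @export
impute_downshift <- function(t, cfg = imputation_config(), cycle_seed = 1) {
  stopifnot(inherits(t, "protein_groups"), inherits(cfg, "imputation_config"))
  if (t$scale != "log2") stop("impute_downshift expects log2-scale intensities")
  X <- t$intensities
  n_obs <- colSums(!t$missing_mask)
  if (any(n_obs < 2))
    stop("sample(s) with fewer than 2 observed values: ",
         paste(colnames(X)[n_obs < 2], collapse = ", "))
  mu <- colMeans(X, na.rm = TRUE)
  sigma <- apply(X, 2, stats::sd, na.rm = TRUE)
  out <- with_seed(cycle_seed, {
    for (s in seq_len(ncol(X))) {
      miss <- which(t$missing_mask[, s])
      if (length(miss))
        X[miss, s] <- stats::rnorm(length(miss),
                                   mean = mu[s] - cfg$downshift_factor * sigma[s],
                                   sd = cfg$width_factor * sigma[s])
    }
    X
  })
  attr(out, "imputed_mask") <- t$missing_mask
  out
}
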