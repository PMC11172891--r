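#' Fold-change-dependent significance curve configuration
#'
#' The significance rule couples the adjusted p-value threshold to the
#' absolute log2 fold change `l`: no protein with `l` at or below
#' `lfc_asymptote` can be called, and the threshold rises from 0 at the
#' asymptote toward `p_max` for large fold changes:
#' `tau(l) = p_max * exp(-c / (l - lfc_asymptote))` for `l > lfc_asymptote`,
#' with curvature `c = curve_factor * sd`, where `sd` is the overall standard
#' deviation of the log2 fold-change vector (or of all intensities, via
#' `sd_reference`). Defaults: `p_max = 0.05`, asymptote at `|log2FC| = 1`
#' (two-fold change), `curve_factor = 0.1`.
#'
#' @param p_max Maximum adjusted p-value at large fold changes.
#' @param lfc_asymptote Log2 fold change at which the threshold reaches 0.
#' @param curve_factor Curvature as a multiple of the reference SD.
#' @param sd_reference `"lfc_sd"` (SD of the log2 fold-change vector,
#'   default) or `"intensity_sd"` (SD of all log2 intensities).
#' @return List of class `significance_curve_config`.
#' @export
significance_curve_config <- function(p_max = 0.05, lfc_asymptote = 1,
                                      curve_factor = 0.1,
                                      sd_reference = c("lfc_sd", "intensity_sd")) {
  check_scalar(p_max, "p_max", lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar(lfc_asymptote, "lfc_asymptote", lower = 0, strict_lower = TRUE)
  check_scalar(curve_factor, "curve_factor", lower = 0)
  sd_reference <- match.arg(sd_reference)
  structure(list(p_max = p_max, lfc_asymptote = lfc_asymptote,
                 curve_factor = curve_factor, sd_reference = sd_reference),
            class = "significance_curve_config")
}

#' Evaluate the significance-curve threshold
#'
#' @param lfc Vector of log2 fold changes (sign ignored).
#' @param curvature The curvature `c` (already multiplied by the reference
#'   SD).
#' @param cfg A [significance_curve_config()].
#' @return The maximum adjusted p-value permitted at each fold change
#'   (0 at or below the asymptote).
#' @export
significance_threshold <- function(lfc, curvature, cfg = significance_curve_config()) {
  l <- abs(lfc)
  tau <- numeric(length(l))
  above <- l > cfg$lfc_asymptote
  tau[above] <- cfg$p_max * exp(-curvature / (l[above] - cfg$lfc_asymptote))
  tau
}

#' Call significance by the fold-change-dependent curve
#'
#' A protein is significant when its BH-adjusted p-value lies at or below the
#' curve threshold at its fold change. The call is monotone: decreasing
#' `p_adj` or increasing `|log2fc|` can never lose significance.
#'
#' @param res A `moderated_t` fit (see [fit_moderated_t()]), or any list with
#'   `log2fc` and `p_adj`.
#' @param cfg A [significance_curve_config()].
#' @param intensity_sd SD of all log2 intensities; required when
#'   `cfg$sd_reference = "intensity_sd"`.
#' @return Logical vector of significance calls, with attributes
#'   `"threshold"` (per-protein tau) and `"curvature"`.
#' @export
significance_call <- function(res, cfg = significance_curve_config(),
                              intensity_sd = NULL) {
  stopifnot(!is.null(res$log2fc), !is.null(res$p_adj))
  sd_ref <- if (cfg$sd_reference == "lfc_sd") stats::sd(res$log2fc)
            else {
              if (is.null(intensity_sd))
                stop("intensity_sd required for sd_reference = 'intensity_sd'")
              intensity_sd
            }
  curvature <- cfg$curve_factor * sd_ref
  tau <- significance_threshold(res$log2fc, curvature, cfg)
  sig <- res$p_adj <= tau & tau > 0
  attr(sig, "threshold") <- tau
  attr(sig, "curvature") <- curvature
  sig
}
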