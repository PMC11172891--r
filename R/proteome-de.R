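# The central fitting function: filter -> variance-stabilising
# renormalisation -> repeated (impute -> moderated t -> BH -> significance
# curve) cycles -> stability flags, returning a classed model object.

# One imputation/testing cycle on a log2-scale table.
de_cycle <- function(t_log2, ann, icfg, scfg, cycle_seed) {
  X <- impute_downshift(t_log2, icfg, cycle_seed = cycle_seed)
  fit <- fit_moderated_t(X, ann)
  sig <- significance_call(fit, scfg, intensity_sd = stats::sd(X))
  list(fit = fit, significant = sig)
}

#' Run the repeated-imputation differential-expression cycles
#'
#' Runs `n_cycles` independent imputation cycles on a filtered, normalised
#' log2-scale table; each cycle imputes, fits the moderated t-test, adjusts
#' by Benjamini-Hochberg and applies the significance curve. Cycle 1 is the
#' reference: its statistics populate the result table and its calls are the
#' `significant` column; `stable` flags proteins significant in every cycle.
#'
#' @param t A log2-scale [protein_groups()].
#' @param ann A [sample_annotation()].
#' @param icfg An [imputation_config()].
#' @param scfg A [significance_curve_config()].
#' @param seed Global integer seed; cycle `k` uses `split_seed(seed, 10 + k)`.
#' @return A `data.frame` (the differential-expression result table) with one
#'   row per protein: `protein_id`, `log2fc`, `s2`, `t_mod`, `df_total`,
#'   `p_raw`, `p_adj`, `threshold`, `significant`, `stable`; per-cycle calls
#'   in attribute `"cycle_calls"`, the reference fit in `"fit"`.
#' @export
stability_flags <- function(t, ann, icfg = imputation_config(),
                            scfg = significance_curve_config(), seed = 1) {
  stopifnot(inherits(t, "protein_groups"))
  if (t$scale != "log2") stop("stability_flags expects a log2-scale table")
  cycles <- lapply(seq_len(icfg$n_cycles), function(k)
    de_cycle(t, ann, icfg, scfg, cycle_seed = split_seed(seed, 10L + k)))
  calls <- vapply(cycles, function(cy) as.logical(cy$significant),
                  logical(nrow(t$intensities)))
  calls <- matrix(calls, nrow = nrow(t$intensities),
                  dimnames = list(t$protein_ids,
                                  paste0("cycle", seq_len(icfg$n_cycles))))
  ref <- cycles[[1]]
  res <- data.frame(
    protein_id = t$protein_ids,
    log2fc = ref$fit$log2fc,
    s2 = ref$fit$s2,
    t_mod = ref$fit$t_mod,
    df_total = ref$fit$df_total,
    p_raw = ref$fit$p_raw,
    p_adj = ref$fit$p_adj,
    threshold = attr(ref$significant, "threshold"),
    significant = as.logical(ref$significant),
    stable = rowSums(calls) == icfg$n_cycles,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "cycle_calls") <- calls
  attr(res, "fit") <- ref$fit
  attr(res, "curvature") <- attr(ref$significant, "curvature")
  res
}

#' Fit the tear-proteome differential-expression model
#'
#' The complete label-free differential-expression procedure on a
#' protein-group table: (1) filter by peptide count, contaminant status and
#' group/sex identification coverage; (2) renormalise raw intensities by the
#' variance-stabilising affine-arsinh calibration ([fit_vsn()]); (3) run
#' repeated downshift-imputation cycles, each followed by the
#' empirical-Bayes moderated t-test, Benjamini-Hochberg adjustment and the
#' fold-change-dependent significance curve; (4) flag proteins whose call is
#' stable across all cycles.
#'
#' @param table A [protein_groups()] on the raw or log2 scale (normalisation
#'   is skipped for log2 input, which is assumed already calibrated).
#' @param annotation A [sample_annotation()] with `group` (cases first
#'   level) and `sex`.
#' @param filter A [filter_config()], or `NULL` to skip filtering.
#' @param imputation An [imputation_config()].
#' @param curve A [significance_curve_config()].
#' @param seed Global integer seed controlling every imputation cycle.
#' @return Object of class `proteome_de`: the result table (`results`), the
#'   filtered table (`table`), annotation, configs, seeds, the filter log,
#'   hyperparameter estimates and the normalisation model (or `NULL`).
#'   Methods: `print`, `summary`, `coef` (log2 fold changes), `plot`
#'   (volcano), `as.data.frame`.
#' @examples
#' sim <- simulate_proteome(proteome_sim_config(n_proteins = 300, seed = 7))
#' fit <- proteome_de(sim$table, sim$annotation,
#'                    imputation = imputation_config(n_cycles = 3), seed = 7)
#' fit
#' head(coef(fit))
#' @export
proteome_de <- function(table, annotation, filter = filter_config(),
                        imputation = imputation_config(),
                        curve = significance_curve_config(), seed = 1) {
  stopifnot(inherits(table, "protein_groups"))
  check_scalar(seed, "seed", integer = TRUE)
  cl <- match.call()
  filtered <- if (is.null(filter)) table
              else filter_protein_groups(table, annotation, filter)
  flog <- attr(filtered, "filter_log")
  norm_model <- NULL
  if (filtered$scale == "raw") {
    norm_model <- fit_vsn(filtered)
    filtered <- apply_vsn(norm_model, filtered)
  }
  res <- stability_flags(filtered, annotation, imputation, curve, seed = seed)
  fit <- attr(res, "fit")
  structure(list(
    results = res,
    table = filtered,
    annotation = align_annotation(annotation, colnames(filtered$intensities)),
    configs = list(filter = filter, imputation = imputation, curve = curve),
    seed = as.integer(seed),
    cycle_seeds = vapply(seq_len(imputation$n_cycles),
                         function(k) split_seed(seed, 10L + k), integer(1)),
    filter_log = flog,
    d0_hat = fit$d0_hat,
    s0sq_hat = fit$s0sq_hat,
    curvature = attr(res, "curvature"),
    normalization = norm_model,
    call = cl
  ), class = "proteome_de")
}

#' @export
print.proteome_de <- function(x, ...) {
  r <- x$results
  cat("Tear-proteome differential expression (moderated t, significance curve)\n")
  cat(sprintf("  %d proteins tested (%d removed by filtering), %d vs %d samples\n",
              nrow(r), if (is.null(x$filter_log)) 0L
                       else sum(x$filter_log) - x$filter_log[["kept"]],
              sum(x$annotation$group == levels(x$annotation$group)[1]),
              sum(x$annotation$group == levels(x$annotation$group)[2])))
  cat(sprintf("  variance prior: d0 = %.3g, s0^2 = %.3g (df residual = %d)\n",
              x$d0_hat, x$s0sq_hat, attr(x$results, "fit")$df_residual))
  cat(sprintf("  significant: %d | stable over %d imputation cycles: %d\n",
              sum(r$significant), x$configs$imputation$n_cycles, sum(r$stable)))
  invisible(x)
}

#' @export
summary.proteome_de <- function(object, ...) {
  r <- object$results
  out <- list(
    n_proteins = nrow(r),
    filter_log = object$filter_log,
    d0_hat = object$d0_hat,
    s0sq_hat = object$s0sq_hat,
    n_significant = sum(r$significant),
    n_stable = sum(r$stable),
    top = r[order(r$p_adj), ][seq_len(min(10, nrow(r))), ]
  )
  class(out) <- "summary.proteome_de"
  out
}

#' @export
print.summary.proteome_de <- function(x, ...) {
  cat("Differential-expression summary\n")
  cat("  filter log:", paste(names(x$filter_log), x$filter_log,
                             sep = "=", collapse = ", "), "\n")
  cat(sprintf("  d0 = %.3g, s0^2 = %.3g; %d significant, %d stable of %d\n",
              x$d0_hat, x$s0sq_hat, x$n_significant, x$n_stable, x$n_proteins))
  cat("  top proteins by adjusted p:\n")
  print(x$top[, c("protein_id", "log2fc", "t_mod", "p_adj",
                  "significant", "stable")], row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.proteome_de <- function(object, ...) {
  stats::setNames(object$results$log2fc, object$results$protein_id)
}

#' @export
as.data.frame.proteome_de <- function(x, ...) x$results

#' Volcano plot of a differential-expression fit
#'
#' Plots `-log10(p_adj)` against the log2 fold change, with the significance
#' curve overlaid; stable significant proteins are shown filled.
#'
#' @param x A `proteome_de` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.proteome_de <- function(x, ...) {
  r <- x$results
  col <- ifelse(r$stable, "firebrick",
                ifelse(r$significant, "orange", "grey50"))
  graphics::plot(r$log2fc, -log10(r$p_adj), pch = 16, cex = 0.5, col = col,
                 xlab = "log2 fold change (cases - controls)",
                 ylab = "-log10 adjusted p", ...)
  cfg <- x$configs$curve
  lmax <- max(abs(r$log2fc), cfg$lfc_asymptote + 1)
  l <- seq(cfg$lfc_asymptote + 1e-3, lmax, length.out = 200)
  tau <- significance_threshold(l, x$curvature, cfg)
  graphics::lines(l, -log10(tau), lty = 2)
  graphics::lines(-l, -log10(tau), lty = 2)
  invisible(x)
}

#' Simulate result tables from the fitted null
#'
#' Draws new null datasets matching the fitted table's dimensions and
#' missingness pattern, with per-protein variances from the fitted prior
#' (`d0_hat`, `s0sq_hat`), and re-runs the testing cycles on each; useful as
#' a parametric-bootstrap check of the significance-curve calibration.
#'
#' @param object A `proteome_de` fit.
#' @param nsim Number of simulated refits.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return List of `nsim` result data frames.
#' @export
simulate.proteome_de <- function(object, nsim = 1, seed = 1, ...) {
  t0 <- object$table
  n_p <- nrow(t0$intensities); n_s <- ncol(t0$intensities)
  base_mu <- rowMeans(t0$intensities, na.rm = TRUE)
  d0 <- if (is.finite(object$d0_hat)) object$d0_hat else 1e6
  lapply(seq_len(nsim), function(i) {
    sub <- split_seed(seed, 100L + i)
    X <- with_seed(sub, {
      sigma2 <- d0 * object$s0sq_hat / stats::rchisq(n_p, d0)
      base_mu + matrix(stats::rnorm(n_p * n_s), n_p, n_s) * sqrt(sigma2)
    })
    dimnames(X) <- dimnames(t0$intensities)
    X[t0$missing_mask] <- NA_real_
    tt <- protein_groups(X, t0$peptide_counts, t0$contaminant_flag,
                         scale = "log2")
    stability_flags(tt, object$annotation, object$configs$imputation,
                    object$configs$curve, seed = sub)
  })
}
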