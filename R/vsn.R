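# Variance-stabilising renormalisation by per-sample affine-arsinh
# (generalised-log) calibration. Each sample s gets a transform
#   h_s(x) = arsinh(a_s + b_s * x) / ln(2),   b_s > 0,
# reported in log2 units so that at high intensities h_s(x) ~ log2(x) + const.
# Parameters are fit by alternating (i) a per-protein reference profile
# (median of transformed values) and (ii) per-sample trimmed least squares of
# the transformed values against the reference. The trimming (fraction 0.1)
# gives robustness to differentially expressed proteins, which by design do
# not follow the reference.

#' Fit a variance-stabilising affine-arsinh calibration
#'
#' @param t A [protein_groups()] on the raw (linear, non-negative) scale with
#'   at least 2 samples.
#' @param trim Fraction of largest squared residuals ignored in each
#'   per-sample fit (default 0.1).
#' @param tol Relative parameter-change convergence tolerance (default 1e-6).
#' @param max_iter Maximum alternation iterations (default 50).
#' @return Object of class `vsn_model` with per-sample offsets `a`, slopes
#'   `b` (> 0), the number of iterations, and a convergence flag.
#' @export
fit_vsn <- function(t, trim = 0.1, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(t, "protein_groups"))
  if (t$scale != "raw")
    stop("fit_vsn expects raw-scale intensities (scale = 'raw')")
  X <- t$intensities
  if (ncol(X) < 2) stop("need at least 2 samples")
  if (any(X < 0, na.rm = TRUE)) stop("negative intensities")

  # Reference rows: proteins observed in all samples when enough exist,
  # otherwise proteins observed in at least 75% of samples (left-censored
  # data can leave few complete cases).
  obs <- !is.na(X)
  complete <- rowSums(obs) == ncol(X)
  ref_rows <- if (sum(complete) >= 30) complete
              else rowSums(obs) >= 0.75 * ncol(X)
  if (sum(ref_rows) < 10)
    stop("too few well-observed proteins to calibrate (need >= 10)")
  Xr <- X[ref_rows, , drop = FALSE]

  n_s <- ncol(X)
  # init: place the glog transition near each sample's low-intensity tail,
  # so the bulk of the data sits in the logarithmic (multiplicative-noise)
  # regime and the transformed values behave like log2 intensities, while
  # the lowest intensities fall in the linear (additive-noise) regime
  b_init <- 1 / apply(Xr, 2, function(x)
    max(stats::quantile(x, 0.02, na.rm = TRUE), 1e-8))
  b <- b_init
  a <- rep(0, n_s)

  trans <- function(x, a1, b1) asinh(a1 + b1 * x)
  ref_profile <- function(a, b) {
    U <- vapply(seq_len(n_s), function(s) trans(Xr[, s], a[s], b[s]),
                numeric(nrow(Xr)))
    apply(U, 1, stats::median, na.rm = TRUE)
  }
  converged <- FALSE
  iter <- 0
  # trim sets adapt during burn-in, then freeze: otherwise borderline
  # proteins flip in and out of the trimmed fraction and the alternation
  # settles into a limit cycle instead of converging
  burn_in <- 15L
  frozen_keep <- vector("list", n_s)
  for (iter in seq_len(max_iter)) {
    ref <- ref_profile(a, b)
    a_new <- a; b_new <- b
    for (s in seq_len(n_s)) {
      fit <- fit_affine_arsinh(Xr[, s], ref, trim = trim,
                               a0 = a[s], b0 = b[s],
                               keep = frozen_keep[[s]])
      a_new[s] <- fit[1]; b_new[s] <- fit[2]
      if (iter == burn_in) frozen_keep[[s]] <- attr(fit, "keep")
    }
    # Gauge fixing: the common rescaling (a, b) -> c * (a, b) and the common
    # offset a -> a + e both leave cross-sample agreement intact (only the
    # shared reference moves), so the alternation is free to drift along
    # them toward degenerate, maximally compressive transforms. Pin both
    # modes: geometric-mean slope ratio to the initial calibration = 1 and
    # mean offset = 0.
    fix_gauge <- function(a, b) {
      g <- exp(mean(log(b / b_init)))
      a <- a / g; b <- b / g
      list(a = a - mean(a), b = b)
    }
    gfix <- fix_gauge(a_new, b_new)
    a_new <- gfix$a; b_new <- gfix$b
    delta <- max(abs(c(a_new - a, b_new - b)) /
                   pmax(abs(c(a, b)), 1e-8))
    a <- a_new; b <- b_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # final polish of the trimmed objective on the arsinh scale, gauge-pinned
  ref <- ref_profile(a, b)
  for (s in seq_len(n_s)) {
    fit <- fit_affine_arsinh(Xr[, s], ref, trim = trim,
                             a0 = a[s], b0 = b[s], polish = TRUE)
    a[s] <- fit[1]; b[s] <- fit[2]
  }
  g <- exp(mean(log(b / b_init)))
  a <- a / g; b <- b / g
  a <- a - mean(a)
  if (!converged)
    warning("vsn calibration did not reach tolerance ", tol, " in ",
            max_iter, " iterations; returning best iterate")
  structure(list(a = a, b = b, samples = colnames(X), trim = trim,
                 iterations = iter, converged = converged),
            class = "vsn_model")
}

# Fit (a, b), b > 0, minimising the trimmed sum of squared residuals
# asinh(a + b x) - ref. Strategy: least-trimmed-squares concentration steps
# using the exact linear solution on the sinh scale (a + b x ~ sinh(ref)),
# which is exact when the sample really is affine in the reference; when
# `polish = TRUE`, a Nelder-Mead refinement of the trimmed objective on the
# arsinh scale follows.
fit_affine_arsinh <- function(x, ref, trim, a0 = 0, b0 = 1, polish = FALSE,
                              keep = NULL) {
  ok <- which(is.finite(x) & is.finite(ref))
  x <- x[ok]; ref <- ref[ok]
  n <- length(x)
  keep_n <- max(2L, ceiling((1 - trim) * n))
  target <- sinh(ref)
  ab <- c(a0, b0)
  if (is.null(keep)) { # least-trimmed-squares concentration steps
    keep <- seq_len(n)
    for (step in 1:5) {
      fit <- stats::lm.fit(cbind(1, x[keep]), target[keep])
      cand <- fit$coefficients
      if (!is.finite(cand[2]) || cand[2] <= 0) break
      ab <- cand
      r2 <- (asinh(ab[1] + ab[2] * x) - ref)^2
      new_keep <- order(r2)[seq_len(keep_n)]
      if (setequal(new_keep, keep)) break
      keep <- new_keep
    }
  } else { # frozen trim set
    fit <- stats::lm.fit(cbind(1, x[keep]), target[keep])
    cand <- fit$coefficients
    if (is.finite(cand[2]) && cand[2] > 0) ab <- cand
  }
  if (!polish) return(structure(c(ab[1], ab[2]), keep = keep))
  obj <- function(par) {
    r2 <- (asinh(par[1] + exp(par[2]) * x) - ref)^2
    sum(sort(r2)[seq_len(keep_n)])
  }
  start <- c(ab[1], log(max(ab[2], 1e-12)))
  pol <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  if (pol$value <= obj(start)) {
    c(pol$par[1], exp(pol$par[2]))
  } else {
    c(ab[1], ab[2])
  }
}

#' Apply a fitted calibration
#'
#' Transforms each sample with its fitted `arsinh(a_s + b_s x) / ln 2`;
#' missing cells remain missing and all other fields are carried over. The
#' transform is strictly increasing in `x` (since `b_s > 0`), so
#' within-sample ranks of observed values are preserved.
#'
#' @param model A `vsn_model` from [fit_vsn()].
#' @param t The raw-scale [protein_groups()] to transform (samples must match
#'   the model).
#' @return A [protein_groups()] on the `"log2"` scale.
#' @export
apply_vsn <- function(model, t) {
  stopifnot(inherits(model, "vsn_model"), inherits(t, "protein_groups"))
  if (t$scale != "raw") stop("apply_vsn expects raw-scale intensities")
  X <- t$intensities
  if (!identical(colnames(X), model$samples))
    stop("samples do not match the fitted model")
  H <- vapply(seq_len(ncol(X)),
              function(s) asinh(model$a[s] + model$b[s] * X[, s]) / log(2),
              numeric(nrow(X)))
  dimnames(H) <- dimnames(X)
  out <- t
  out$intensities <- H
  out$scale <- "log2"
  out
}
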