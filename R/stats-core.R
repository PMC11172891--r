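# Self-contained implementations of the elementary tests used downstream.
# These are deliberately written out rather than delegated, so that every
# numerical convention (two-sided rules, tie handling, permutation p-value
# formula) is explicit and testable against independent references.

#' Two-sample summary statistics
#'
#' @param n1,n2 Group sizes (each at least 2).
#' @param mean1,mean2 Group means.
#' @param var1,var2 Group sample variances (non-negative).
#' @return A list of class `two_sample_summary`.
#' @export
two_sample_summary <- function(n1, n2, mean1, mean2, var1, var2) {
  check_scalar(n1, "n1", lower = 2, integer = TRUE)
  check_scalar(n2, "n2", lower = 2, integer = TRUE)
  check_scalar(mean1, "mean1"); check_scalar(mean2, "mean2")
  check_scalar(var1, "var1", lower = 0)
  check_scalar(var2, "var2", lower = 0)
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2),
                 mean1 = mean1, mean2 = mean2, var1 = var1, var2 = var2),
            class = "two_sample_summary")
}

#' Welch's unequal-variance t-test from summary statistics
#'
#' Computes `t = (mean2 - mean1) / sqrt(var1/n1 + var2/n2)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' central t distribution. Operating on summaries (rather than raw vectors)
#' allows published tables of group means and variances to be checked
#' directly.
#'
#' @param s A [two_sample_summary()], or a numeric vector (group 1) when `y`
#'   is given.
#' @param y Optional numeric vector (group 2); when supplied, summaries are
#'   computed from the two raw vectors.
#' @return List with elements `t`, `df`, `p` (two-sided).
#' @export
welch_t_test <- function(s, y = NULL) {
  if (!is.null(y)) {
    x <- as.numeric(s); y <- as.numeric(y)
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    s <- two_sample_summary(length(x), length(y), mean(x), mean(y),
                            stats::var(x), stats::var(y))
  }
  stopifnot(inherits(s, "two_sample_summary"))
  se2 <- s$var1 / s$n1 + s$var2 / s$n2
  delta <- s$mean2 - s$mean1
  if (se2 == 0) {
    if (delta == 0) return(list(t = 0, df = Inf, p = 1))
    warning("both variances are zero with unequal means; p set to 0")
    return(list(t = sign(delta) * Inf, df = Inf, p = 0))
  }
  t <- delta / sqrt(se2)
  df <- se2^2 / ((s$var1 / s$n1)^2 / (s$n1 - 1) + (s$var2 / s$n2)^2 / (s$n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact enumeration over all tables with the observed margins; the two-sided
#' p-value is the sum of hypergeometric probabilities of tables whose
#' probability does not exceed the observed table's (probability-mass rule,
#' with a relative tie tolerance of 1e-7).
#'
#' @param tab 2x2 matrix of non-negative integer counts; rows are groups,
#'   columns are positive/negative status.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 + r2 == 0) stop("empty table")
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  n <- r1 + r2
  # feasible values of the (1,1) cell given the margins
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(k, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-squared test for a 2x2 table
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param yates Apply the Yates continuity correction.
#' @return List with `chi2` and `p` (df = 1).
#' @export
pearson_chi2_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) {
    bad <- which(expected == 0, arr.ind = TRUE)[1, ]
    stop("expected count is zero in cell [", bad[1], ",", bad[2], "]")
  }
  dev <- abs(tab - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  chi2 <- sum(dev^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: sort p ascending, form `p_i * m / i`, enforce
#' monotonicity by a cumulative minimum from the largest rank, cap at 1, and
#' return in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0) {
    o <- order(pv)
    adj <- pv[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    adj <- pmin(adj, 1)
    qv <- numeric(m)
    qv[o] <- adj
    q[ok] <- qv
  }
  q
}

#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` (natural logarithm) over the renormalised
#' nonzero components of a composition.
#'
#' @param abundances Non-negative vector; relative or absolute abundances.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(abundances) {
  x <- as.numeric(abundances)
  if (any(!is.finite(x)) || any(x < 0)) stop("abundances must be finite and >= 0")
  if (sum(x) == 0) stop("all-zero composition has no Shannon index")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Principal component analysis by singular value decomposition
#'
#' Columns (features) are centred, and unit-scaled when `scale = TRUE`;
#' zero-variance features are dropped (with a message) before scaling. The
#' sign of each component is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param scale Scale features to unit variance.
#' @return List with `scores` (samples x components), `loadings`
#'   (features x components), `explained_variance` (proportions), `sdev`, and
#'   `dropped` (names/indices of zero-variance features removed).
#' @export
pca <- function(X, scale = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 samples")
  v <- apply(X, 2, stats::var)
  dropped <- which(v == 0 | !is.finite(v))
  if (length(dropped)) {
    message("dropping ", length(dropped), " zero-variance feature(s) before PCA")
    X <- X[, -dropped, drop = FALSE]
  }
  if (ncol(X) < 2) stop("fewer than 2 usable features")
  Xc <- base::scale(X, center = TRUE, scale = scale)
  s <- svd(Xc)
  ncomp <- sum(s$d > s$d[1] * 1e-12)
  scores <- s$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(s$d[seq_len(ncomp)], ncomp)
  loadings <- s$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  sdev <- s$d[seq_len(ncomp)] / sqrt(nrow(X) - 1)
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(ncomp))
  list(scores = scores, loadings = loadings,
       explained_variance = sdev^2 / sum(sdev^2), sdev = sdev,
       dropped = dropped)
}

# Pseudo-F from a squared-distance matrix and an integer group coding.
# SS_total = sum_{i<j} d^2 / n ; SS_within = sum_g sum_{i<j in g} d^2 / n_g.
permanova_f <- function(D2, groups) {
  n <- nrow(D2)
  a <- length(unique(groups))
  ss_total <- sum(D2) / (2 * n)
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(f = f, ss_between = ss_between, ss_within = ss_within)
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a pairwise distance matrix: the pseudo-F compares
#' between-group to within-group sums of squared distances, and significance
#' is assessed by permuting group labels. The p-value uses the add-one rule
#' `p = (#{F_perm >= F_obs} + 1) / (n_perm + 1)`, so it can never be zero.
#'
#' @param D Symmetric distance matrix (zero diagonal) or `dist` object.
#' @param labels Group assignment, one per observation; at least 2 groups
#'   with at least 2 members each.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `SS_between`, `SS_within`.
#' @export
permanova <- function(D, labels, n_perm = 1000, seed = 1) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  D <- as.matrix(D)
  n <- nrow(D)
  if (ncol(D) != n || any(abs(D - t(D)) > 1e-8))
    stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  labels <- as.integer(as.factor(labels))
  if (length(labels) != n) stop("labels length mismatch")
  sizes <- table(labels)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need at least 2 groups with at least 2 members each")
  check_scalar(n_perm, "n_perm", lower = 1, integer = TRUE)
  D2 <- D^2
  obs <- permanova_f(D2, labels)
  f_perm <- with_seed(split_seed(seed, 0L), {
    vapply(seq_len(n_perm),
           function(i) permanova_f(D2, sample(labels))[["f"]],
           numeric(1))
  })
  p <- (sum(f_perm >= obs[["f"]]) + 1) / (n_perm + 1)
  structure(list(pseudo_F = obs[["f"]], p_value = p,
                 n_permutations = as.integer(n_perm),
                 SS_between = obs[["ss_between"]],
                 SS_within = obs[["ss_within"]]),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$p_value, x$n_permutations))
  invisible(x)
}
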