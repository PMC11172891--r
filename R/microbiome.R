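# Taxon relative-abundance container and the downstream microbiome
# summaries: rank aggregation, "Under 1%" lumping, Shannon diversity
# comparison, presence/absence association, and community-level PCA +
# PERMANOVA.

TAXON_RANKS <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                 f = "family", g = "genus", s = "species")

#' Taxon relative-abundance table
#'
#' @param abundances Numeric matrix, taxa in rows (rownames are
#'   profiler-style lineage strings such as
#'   `"k__Bacteria|p__Firmicutes|g__Staphylococcus|s__Staphylococcus_aureus"`),
#'   samples in columns. Non-negative; per-sample totals at most 1 (fraction
#'   scale) or 100 (percent scale), up to rounding.
#' @param scale `"fraction"` or `"percent"`.
#' @return Object of class `taxon_abundance`.
#' @export
taxon_abundance <- function(abundances, scale = c("fraction", "percent")) {
  scale <- match.arg(scale)
  x <- as.matrix(abundances)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) stop("abundance rows must be named by lineage")
  if (any(!is.finite(x)) || any(x < 0))
    stop("abundances must be finite and >= 0")
  total_cap <- if (scale == "percent") 100 else 1
  if (any(colSums(x) > total_cap * (1 + 1e-6)))
    stop("per-sample totals exceed the ", scale, " scale")
  structure(list(abundances = x, scale = scale), class = "taxon_abundance")
}

#' @export
print.taxon_abundance <- function(x, ...) {
  cat("Taxon abundance table:", nrow(x$abundances), "taxa x",
      ncol(x$abundances), "samples (", x$scale, "scale )\n")
  invisible(x)
}

# Extract the label of `rank` from each lineage string; NA when the rank
# prefix is absent.
parse_rank <- function(lineages, rank) {
  prefix <- names(TAXON_RANKS)[match(rank, TAXON_RANKS)]
  if (is.na(prefix)) stop("unknown taxonomic rank: ", rank)
  out <- rep(NA_character_, length(lineages))
  parts <- strsplit(lineages, "|", fixed = TRUE)
  pat <- paste0("^", prefix, "__")
  for (i in seq_along(parts)) {
    hit <- grep(pat, parts[[i]], value = TRUE)
    if (length(hit)) out[i] <- sub(pat, "", hit[1])
  }
  out
}

#' Aggregate a taxon table at a taxonomic rank
#'
#' Sums abundances of all taxa sharing the same label at the requested rank;
#' per-sample totals are preserved. Taxa whose lineage lacks the rank are
#' collected under `"unclassified"`.
#'
#' @param t A [taxon_abundance()].
#' @param rank One of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return A [taxon_abundance()] with one row per rank label.
#' @export
aggregate_level <- function(t, rank = "phylum") {
  stopifnot(inherits(t, "taxon_abundance"))
  labels <- parse_rank(rownames(t$abundances), rank)
  labels[is.na(labels)] <- "unclassified"
  agg <- rowsum(t$abundances, group = labels, reorder = TRUE)
  taxon_abundance(agg, scale = t$scale)
}

#' Lump low-abundance taxa into an "Under 1%" row
#'
#' Taxa whose mean abundance is below `threshold_percent` within every
#' comparison group (or overall, when `ann` is `NULL` or `per = "sample"`)
#' are removed and their per-sample sum reported as the taxon `"Under 1%"`;
#' per-sample totals are preserved exactly.
#'
#' @param t A [taxon_abundance()].
#' @param ann Optional [sample_annotation()] defining the comparison groups.
#' @param threshold_percent Threshold on the percent scale (default 1).
#' @param per `"group"` (default): lump taxa rare in every group mean;
#'   `"overall"`: lump taxa rare in the overall mean.
#' @return A [taxon_abundance()] with retained taxa plus an `"Under 1%"` row
#'   (present only when something was lumped).
#' @export
lump_rare <- function(t, ann = NULL, threshold_percent = 1,
                      per = c("group", "overall")) {
  stopifnot(inherits(t, "taxon_abundance"))
  per <- match.arg(per)
  x <- t$abundances
  to_percent <- if (t$scale == "percent") 1 else 100
  if (per == "group" && !is.null(ann)) {
    ann <- align_annotation(ann, colnames(x))
    rare <- rep(TRUE, nrow(x))
    for (g in levels(droplevels(ann$group))) {
      gm <- rowMeans(x[, ann$group == g, drop = FALSE]) * to_percent
      rare <- rare & (gm < threshold_percent)
    }
  } else {
    rare <- rowMeans(x) * to_percent < threshold_percent
  }
  if (!any(rare)) return(t)
  kept <- x[!rare, , drop = FALSE]
  lump <- colSums(x[rare, , drop = FALSE])
  out <- rbind(kept, "Under 1%" = lump)
  taxon_abundance(out, scale = t$scale)
}

#' Compare Shannon diversity between two groups
#'
#' Computes the per-sample Shannon index ([shannon_index()]) and compares
#' groups with Welch's t-test.
#'
#' @param t A [taxon_abundance()].
#' @param ann A [sample_annotation()]; the first two group levels are
#'   compared (group 1 vs group 2).
#' @return List of class `group_comparison`: `statistic`, `p_value`,
#'   per-group summaries, and the per-sample index values.
#' @export
diversity_compare <- function(t, ann) {
  stopifnot(inherits(t, "taxon_abundance"))
  ann <- align_annotation(ann, colnames(t$abundances))
  H <- apply(t$abundances, 2, shannon_index)
  gl <- levels(droplevels(ann$group))
  if (length(gl) < 2 || any(table(ann$group)[gl[1:2]] < 2))
    stop("need at least 2 samples per group")
  h1 <- H[ann$group == gl[1]]; h2 <- H[ann$group == gl[2]]
  wt <- welch_t_test(h1, h2)
  structure(list(method = "Shannon index, Welch t-test",
                 statistic = wt$t, df = wt$df, p_value = wt$p,
                 group_means = stats::setNames(c(mean(h1), mean(h2)), gl[1:2]),
                 index = H),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$method, "\n  p =", format(x$p_value, digits = 3), "\n")
  invisible(x)
}

#' Presence/absence association of one taxon with group membership
#'
#' A sample is positive when the taxon's abundance exceeds
#' `detection_threshold` (default 0: any nonzero abundance, so the call is
#' invariant to percent-vs-fraction scaling). The resulting 2x2 table
#' (groups x positive/negative) is tested with [fisher_exact_2x2()].
#'
#' @param t A [taxon_abundance()].
#' @param ann A [sample_annotation()].
#' @param taxon Lineage string or a unique substring of it (e.g. a species
#'   name).
#' @param detection_threshold Abundance above which a sample counts as
#'   positive.
#' @return List of class `group_comparison` with the contingency `table` and
#'   Fisher `p_value`.
#' @export
presence_absence_test <- function(t, ann, taxon, detection_threshold = 0) {
  stopifnot(inherits(t, "taxon_abundance"))
  ann <- align_annotation(ann, colnames(t$abundances))
  row <- which(rownames(t$abundances) == taxon)
  if (!length(row))
    row <- grep(taxon, rownames(t$abundances), fixed = TRUE)
  if (!length(row)) stop("taxon '", taxon, "' not found in the table")
  if (length(row) > 1) stop("taxon '", taxon, "' matches multiple rows")
  pos <- t$abundances[row, ] > detection_threshold
  gl <- levels(droplevels(ann$group))
  tab <- rbind(c(sum(pos[ann$group == gl[1]]), sum(!pos[ann$group == gl[1]])),
               c(sum(pos[ann$group == gl[2]]), sum(!pos[ann$group == gl[2]])))
  dimnames(tab) <- list(gl[1:2], c("positive", "negative"))
  structure(list(method = "presence/absence, two-sided Fisher exact test",
                 table = tab, p_value = fisher_exact_2x2(tab),
                 taxon = rownames(t$abundances)[row]),
            class = "group_comparison")
}

#' Community-level comparison: PCA and PERMANOVA on scaled abundances
#'
#' Feature-scales the taxon matrix (samples x taxa, zero mean / unit variance
#' per taxon), runs [pca()], and tests group separation with [permanova()] on
#' the corresponding distances of the scaled matrix (Euclidean by default;
#' Bray-Curtis on the raw relative abundances as an option).
#'
#' @param t A [taxon_abundance()].
#' @param ann A [sample_annotation()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @param distance `"euclidean"` (on the scaled matrix) or `"bray"` (on the
#'   untransformed relative abundances).
#' @return List with `pca` (see [pca()]) and `permanova`
#'   ([permanova()] result).
#' @export
community_comparison <- function(t, ann, n_perm = 1000, seed = 1,
                                 distance = c("euclidean", "bray")) {
  stopifnot(inherits(t, "taxon_abundance"))
  distance <- match.arg(distance)
  ann <- align_annotation(ann, colnames(t$abundances))
  if (ncol(t$abundances) < 3) stop("need at least 3 samples")
  M <- t(t$abundances) # samples x taxa
  pc <- pca(M, scale = TRUE)
  if (distance == "euclidean") {
    keep <- apply(M, 2, stats::var) > 0
    D <- as.matrix(stats::dist(base::scale(M[, keep, drop = FALSE])))
  } else {
    num <- as.matrix(stats::dist(M, method = "manhattan"))
    denom <- outer(rowSums(M), rowSums(M), "+")
    D <- num / denom
    diag(D) <- 0
  }
  pm <- permanova(D, ann$group, n_perm = n_perm, seed = seed)
  list(pca = pc, permanova = pm)
}
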