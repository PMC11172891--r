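# Tab-separated readers and writers for the two table types, plus the
# results writer with a JSON provenance report. All files are UTF-8 TSV with
# "." as the decimal separator; empty intensity cells mean missing.

#' Read a protein-group table from TSV
#'
#' Expected columns: `protein_id`, `peptide_count`, `contaminant`
#' (TRUE/FALSE or 0/1), then one intensity column per sample. Empty cells
#' and `NA` are missing values.
#'
#' @param path Path to the TSV file.
#' @param scale `"raw"` or `"log2"`, the scale of the stored intensities.
#' @return A [protein_groups()].
#' @export
read_protein_table <- function(path, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  required <- c("protein_id", "peptide_count", "contaminant")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("protein table lacks column(s): ", paste(missing_cols, collapse = ", "))
  sample_cols <- setdiff(names(df), required)
  if (!length(sample_cols)) stop("protein table has no intensity columns")
  X <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- sample_cols[!vapply(df[sample_cols], is.numeric, logical(1))]
    stop("non-numeric intensity column(s): ", paste(bad, collapse = ", "))
  }
  rownames(X) <- df$protein_id
  protein_groups(X, peptide_counts = df$peptide_count,
                 contaminant_flag = as.logical(df$contaminant),
                 protein_ids = df$protein_id, scale = scale)
}

#' Write a protein-group table to TSV
#'
#' Inverse of [read_protein_table()]; missing cells are written empty.
#'
#' @param t A [protein_groups()].
#' @param path Output path.
#' @export
write_protein_table <- function(t, path) {
  stopifnot(inherits(t, "protein_groups"))
  df <- data.frame(protein_id = t$protein_ids,
                   peptide_count = t$peptide_counts,
                   contaminant = t$contaminant_flag,
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(t$intensities, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a taxonomic relative-abundance table from profiler-style TSV
#'
#' Rows are pipe-separated, rank-prefixed lineage strings (e.g.
#' `k__Bacteria|p__Firmicutes|...|s__Staphylococcus_aureus`) in the first
#' column; remaining columns are per-sample abundances. Rows whose lineage
#' carries no recognisable rank prefix are skipped with a warning giving the
#' count.
#'
#' @param path Path to the TSV file.
#' @param scale `"percent"` or `"fraction"`.
#' @return A [taxon_abundance()].
#' @export
read_abundance_table <- function(path, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lineages <- as.character(df[[1]])
  X <- as.matrix(df[, -1, drop = FALSE])
  ok <- grepl("(^|\\|)[kpcofgs]__", lineages)
  if (!all(ok)) {
    warning("skipping ", sum(!ok), " row(s) with unparseable lineage strings")
    X <- X[ok, , drop = FALSE]
    lineages <- lineages[ok]
  }
  rownames(X) <- lineages
  taxon_abundance(X, scale = scale)
}

#' Write a taxon abundance table to TSV
#' @param t A [taxon_abundance()].
#' @param path Output path.
#' @export
write_abundance_table <- function(t, path) {
  stopifnot(inherits(t, "taxon_abundance"))
  df <- data.frame(lineage = rownames(t$abundances),
                   as.data.frame(t$abundances, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write differential-expression results with a provenance report
#'
#' Writes the per-protein result table as `de_results.tsv` and a JSON run
#' report (`report.json`) with the package version, all configuration
#' values, the global and per-cycle seeds, and the per-rule filter log —
#' enough to reproduce the run bit-identically.
#'
#' @param fit A `proteome_de` fit.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_de_results <- function(fit, dir) {
  stopifnot(inherits(fit, "proteome_de"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "de_results.tsv")
  utils::write.table(fit$results, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- list(
    package = "tearosm",
    version = as.character(utils::packageVersion("tearosm")),
    seed = fit$seed,
    cycle_seeds = fit$cycle_seeds,
    configs = lapply(fit$configs, function(cfg)
      if (is.null(cfg)) NULL else unclass(cfg)),
    filter_log = as.list(fit$filter_log),
    d0_hat = fit$d0_hat,
    s0sq_hat = fit$s0sq_hat,
    curvature = fit$curvature,
    n_proteins = nrow(fit$results),
    n_significant = sum(fit$results$significant),
    n_stable = sum(fit$results$stable)
  )
  json <- file.path(dir, "report.json")
  jsonlite::write_json(report, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(tsv, json))
}
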