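#' Protein-group quantification table
#'
#' Container for a label-free quantification protein-group matrix: intensities
#' (proteins x samples), an explicit missingness mask, per-protein identified
#' peptide counts, and a contaminant flag. Intensities may be on the raw
#' (linear) scale as exported by search engines, or already log2-transformed;
#' the `scale` field records which.
#'
#' @param intensities Numeric matrix, proteins in rows, samples in columns.
#'   `NA` cells are treated as missing.
#' @param peptide_counts Integer vector, identified peptides per protein.
#' @param contaminant_flag Logical vector, `TRUE` for contaminant entries
#'   (search-engine annotation). Defaults to all `FALSE`.
#' @param protein_ids Character vector of unique protein-group identifiers.
#'   Defaults to the matrix rownames.
#' @param scale Either `"raw"` (linear intensities, non-negative) or `"log2"`.
#' @return An object of class `protein_groups`: a list with fields
#'   `intensities`, `missing_mask`, `peptide_counts`, `contaminant_flag`,
#'   `protein_ids`, `scale`.
#' @export
protein_groups <- function(intensities, peptide_counts,
                           contaminant_flag = NULL, protein_ids = NULL,
                           scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  n <- nrow(intensities)
  if (is.null(protein_ids)) protein_ids <- rownames(intensities)
  if (is.null(protein_ids)) protein_ids <- sprintf("P%05d", seq_len(n))
  protein_ids <- as.character(protein_ids)
  if (anyDuplicated(protein_ids))
    stop("duplicate protein ids: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  if (length(protein_ids) != n)
    stop("protein_ids length does not match intensity rows")
  if (length(peptide_counts) != n)
    stop("peptide_counts length does not match intensity rows")
  peptide_counts <- as.integer(peptide_counts)
  if (any(is.na(peptide_counts)) || any(peptide_counts < 0))
    stop("peptide_counts must be non-negative integers")
  if (is.null(contaminant_flag)) contaminant_flag <- rep(FALSE, n)
  contaminant_flag <- as.logical(contaminant_flag)
  if (length(contaminant_flag) != n || any(is.na(contaminant_flag)))
    stop("contaminant_flag must be logical of length nrow(intensities)")
  if (scale == "raw" && any(intensities < 0, na.rm = TRUE))
    stop("raw-scale intensities must be non-negative")
  rownames(intensities) <- protein_ids
  structure(list(
    intensities = intensities,
    missing_mask = is.na(intensities),
    peptide_counts = peptide_counts,
    contaminant_flag = contaminant_flag,
    protein_ids = protein_ids,
    scale = scale
  ), class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat("Protein-group table:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "samples (", x$scale, "scale )\n")
  cat("  missing cells:", sum(x$missing_mask),
      sprintf("(%.1f%%)", 100 * mean(x$missing_mask)), "\n")
  cat("  contaminants flagged:", sum(x$contaminant_flag),
      "| proteins with < 2 peptides:", sum(x$peptide_counts < 2), "\n")
  invisible(x)
}

#' @export
dim.protein_groups <- function(x) dim(x$intensities)

# Subset proteins (logical or integer index), keeping all per-protein fields
# aligned.
subset_proteins <- function(x, keep) {
  stopifnot(inherits(x, "protein_groups"))
  x$intensities <- x$intensities[keep, , drop = FALSE]
  x$missing_mask <- x$missing_mask[keep, , drop = FALSE]
  x$peptide_counts <- x$peptide_counts[keep]
  x$contaminant_flag <- x$contaminant_flag[keep]
  x$protein_ids <- x$protein_ids[keep]
  x
}

#' Per-sample annotation table
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Factor or character; must contain the levels `"patient"` and
#'   `"control"` semantics of a two-group design (any two labels accepted).
#' @param sex Factor or character with values `"female"`/`"male"` (optional
#'   for microbiome-only workflows).
#' @param age Numeric vector of ages in years (optional).
#' @return A `data.frame` of class `sample_annotation`.
#' @export
sample_annotation <- function(sample_id, group, sex = NULL, age = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  n <- length(sample_id)
  # first level = first group encountered (the case group), not alphabetical
  if (!is.factor(group)) group <- factor(group, levels = unique(as.character(group)))
  if (length(group) != n) stop("group length mismatch")
  if (nlevels(droplevels(group)) < 2)
    stop("annotation must contain at least two groups")
  ann <- data.frame(sample_id = sample_id, group = group,
                    stringsAsFactors = FALSE)
  if (!is.null(sex)) {
    sex <- as.factor(sex)
    if (length(sex) != n) stop("sex length mismatch")
    ann$sex <- sex
  }
  if (!is.null(age)) {
    if (length(age) != n) stop("age length mismatch")
    ann$age <- as.numeric(age)
  }
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

# Align annotation rows to the column order of an intensity matrix.
align_annotation <- function(ann, sample_ids) {
  idx <- match(sample_ids, ann$sample_id)
  if (anyNA(idx))
    stop("annotation is missing samples: ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  ann[idx, , drop = FALSE]
}
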