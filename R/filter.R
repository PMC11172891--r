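#' Filtering configuration for protein groups
#'
#' Defaults follow the standard tear-proteome workflow: drop protein groups
#' with fewer than 2 identified peptides, then contaminants, then groups
#' identified in fewer than 8 patients or fewer than 8 controls, then groups
#' identified in fewer than 9 female or fewer than 8 male samples.
#'
#' @param min_peptides Minimum identified peptides (default 2).
#' @param min_ids_per_group Minimum identifications (non-missing cells)
#'   required in each study group (default 8).
#' @param min_ids_female,min_ids_male Minimum identifications required among
#'   female / male samples (defaults 9 and 8).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(min_peptides = 2, min_ids_per_group = 8,
                          min_ids_female = 9, min_ids_male = 8) {
  check_scalar(min_peptides, "min_peptides", lower = 0, integer = TRUE)
  check_scalar(min_ids_per_group, "min_ids_per_group", lower = 0, integer = TRUE)
  check_scalar(min_ids_female, "min_ids_female", lower = 0, integer = TRUE)
  check_scalar(min_ids_male, "min_ids_male", lower = 0, integer = TRUE)
  structure(as.list(environment()), class = "filter_config")
}

#' Filter protein groups by peptide count, contaminant status and
#' identification coverage
#'
#' Rules are applied in order: (1) peptide count below `min_peptides`;
#' (2) contaminant flag; (3) identification count below `min_ids_per_group`
#' in either study group; (4) identification count below `min_ids_female`
#' among female samples or below `min_ids_male` among male samples. Each
#' protein is charged to the first rule that removes it; the per-rule removal
#' log is attached as attribute `"filter_log"`.
#'
#' @param t A [protein_groups()].
#' @param ann A [sample_annotation()] covering all samples, with `sex` when
#'   rule 4 thresholds are positive.
#' @param cfg A [filter_config()].
#' @return The filtered [protein_groups()] with attribute `filter_log` (named
#'   integer vector of per-rule removal counts plus `kept`).
#' @export
filter_protein_groups <- function(t, ann, cfg = filter_config()) {
  stopifnot(inherits(t, "protein_groups"), inherits(cfg, "filter_config"))
  ann <- align_annotation(ann, colnames(t$intensities))
  gl <- levels(droplevels(ann$group))
  ids <- !t$missing_mask
  for (g in gl) {
    if (cfg$min_ids_per_group > sum(ann$group == g))
      stop("min_ids_per_group exceeds the size of group '", g, "'")
  }
  rule1 <- t$peptide_counts < cfg$min_peptides
  rule2 <- !rule1 & t$contaminant_flag
  per_group_ok <- rep(TRUE, nrow(ids))
  for (g in gl) {
    cnt <- rowSums(ids[, ann$group == g, drop = FALSE])
    per_group_ok <- per_group_ok & (cnt >= cfg$min_ids_per_group)
  }
  rule3 <- !rule1 & !rule2 & !per_group_ok
  rule4 <- rep(FALSE, nrow(ids))
  if (cfg$min_ids_female > 0 || cfg$min_ids_male > 0) {
    if (is.null(ann$sex))
      stop("annotation lacks 'sex' but sex-stratified thresholds are set")
    n_f <- sum(ann$sex == "female"); n_m <- sum(ann$sex == "male")
    if (cfg$min_ids_female > n_f)
      stop("min_ids_female exceeds the size of the female stratum")
    if (cfg$min_ids_male > n_m)
      stop("min_ids_male exceeds the size of the male stratum")
    cnt_f <- rowSums(ids[, ann$sex == "female", drop = FALSE])
    cnt_m <- rowSums(ids[, ann$sex == "male", drop = FALSE])
    rule4 <- !rule1 & !rule2 & !rule3 &
      (cnt_f < cfg$min_ids_female | cnt_m < cfg$min_ids_male)
  }
  keep <- !(rule1 | rule2 | rule3 | rule4)
  out <- subset_proteins(t, keep)
  attr(out, "filter_log") <- c(
    low_peptides = sum(rule1), contaminant = sum(rule2),
    group_coverage = sum(rule3), sex_coverage = sum(rule4),
    kept = sum(keep))
  out
}
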