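# Synthetic ocular-surface microbiome generator: Dirichlet compositions over
# a small species panel dominated by Actinobacteria / Firmicutes /
# Proteobacteria, plus one marker species whose presence probability differs
# between groups (to exercise the presence/absence Fisher test).

# Default species panel with profiler-style lineage strings. Concentrations
# are proportional to typical ocular-surface mean relative abundances, with
# Cutibacterium acnes, Limosilactobacillus fermentum and Staphylococcus
# aureus as the dominant species.
default_taxon_panel <- function() {
  lin <- function(p, g, s)
    sprintf("k__Bacteria|p__%s|g__%s|s__%s", p, g, s)
  data.frame(
    lineage = c(
      lin("Actinobacteria", "Cutibacterium", "Cutibacterium_acnes"),
      lin("Actinobacteria", "Corynebacterium", "Corynebacterium_mastitidis"),
      lin("Actinobacteria", "Corynebacterium", "Corynebacterium_accolens"),
      lin("Actinobacteria", "Micrococcus", "Micrococcus_luteus"),
      lin("Firmicutes", "Limosilactobacillus", "Limosilactobacillus_fermentum"),
      lin("Firmicutes", "Staphylococcus", "Staphylococcus_aureus"),
      lin("Firmicutes", "Staphylococcus", "Staphylococcus_epidermidis"),
      lin("Firmicutes", "Streptococcus", "Streptococcus_mitis"),
      lin("Proteobacteria", "Pseudomonas", "Pseudomonas_aeruginosa"),
      lin("Proteobacteria", "Moraxella", "Moraxella_osloensis"),
      lin("Proteobacteria", "Acinetobacter", "Acinetobacter_johnsonii"),
      lin("Bacteroidetes", "Prevotella", "Prevotella_melaninogenica")
    ),
    concentration = c(24, 1.5, 6, 5, 15.5, 10, 6, 5.5, 12, 6, 4, 3),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic microbiome generator
#'
#' @param taxa Data frame with columns `lineage` (profiler-style
#'   pipe-separated, rank-prefixed strings) and `concentration` (positive
#'   Dirichlet concentration weights). Defaults to a 12-species ocular-surface
#'   panel.
#' @param n_per_group Integer pair: samples in (patients, controls).
#' @param marker_taxon Lineage (or species name) of the group-restricted
#'   marker; must be in `taxa`. `NULL` disables the marker mechanism.
#' @param marker_taxon_prevalence Numeric pair: probability that the marker is
#'   present in a (patient, control) sample. Defaults to (0, 7/16), the
#'   presence pattern of a marker absent from patients and found in 7 of 16
#'   controls.
#' @param overdispersion Scalar multiplier on the concentration vector;
#'   smaller values give noisier compositions.
#' @param seed Integer seed.
#' @return List of class `microbiome_sim_config`.
#' @export
microbiome_sim_config <- function(taxa = default_taxon_panel(),
                                  n_per_group = c(16, 16),
                                  marker_taxon = "Corynebacterium_mastitidis",
                                  marker_taxon_prevalence = c(0, 7 / 16),
                                  overdispersion = 1,
                                  seed = 1) {
  stopifnot(is.data.frame(taxa), all(c("lineage", "concentration") %in% names(taxa)))
  if (any(!is.finite(taxa$concentration)) || any(taxa$concentration <= 0))
    stop("config field 'taxa$concentration' must be positive and finite")
  stopifnot(length(n_per_group) == 2)
  check_scalar(n_per_group[1], "n_per_group[1]", lower = 1, integer = TRUE)
  check_scalar(n_per_group[2], "n_per_group[2]", lower = 1, integer = TRUE)
  check_scalar(marker_taxon_prevalence[1], "marker_taxon_prevalence[1]",
               lower = 0, upper = 1)
  check_scalar(marker_taxon_prevalence[2], "marker_taxon_prevalence[2]",
               lower = 0, upper = 1)
  check_scalar(overdispersion, "overdispersion", lower = 0, strict_lower = TRUE)
  check_scalar(seed, "seed", integer = TRUE)
  if (!is.null(marker_taxon) &&
      !any(grepl(marker_taxon, taxa$lineage, fixed = TRUE)))
    stop("marker taxon '", marker_taxon, "' not found in the taxon panel")
  structure(as.list(environment()), class = "microbiome_sim_config")
}

#' Simulate two-group microbial relative-abundance profiles with ground truth
#'
#' Per-sample compositions are Dirichlet draws over the configured species
#' panel. The marker species is present (Bernoulli, group-specific
#' probability) or structurally absent; each composition is renormalised to
#' sum to one after zeroing an absent marker.
#'
#' @param config A [microbiome_sim_config()].
#' @return List with `table` ([taxon_abundance()], fraction scale),
#'   `annotation`, and `truth` (class `sim_truth`: per-sample
#'   `marker_presence`, the marker lineage, and the concentration vector).
#' @export
simulate_microbiome <- function(config = microbiome_sim_config()) {
  stopifnot(inherits(config, "microbiome_sim_config"))
  cfg <- config
  n_pat <- cfg$n_per_group[1]; n_ctl <- cfg$n_per_group[2]
  n_s <- n_pat + n_ctl
  n_t <- nrow(cfg$taxa)
  sample_id <- c(sprintf("PAT%02d", seq_len(n_pat)),
                 sprintf("CTL%02d", seq_len(n_ctl)))
  group <- factor(rep(c("patient", "control"), c(n_pat, n_ctl)),
                  levels = c("patient", "control"))
  marker_row <- if (is.null(cfg$marker_taxon)) NA_integer_
                else which(grepl(cfg$marker_taxon, cfg$taxa$lineage,
                                 fixed = TRUE))[1]
  alpha <- cfg$taxa$concentration * cfg$overdispersion

  out <- with_seed(split_seed(cfg$seed, 3L), {
    present <- if (is.na(marker_row)) rep(NA, n_s)
               else stats::runif(n_s) <
                 ifelse(group == "patient", cfg$marker_taxon_prevalence[1],
                        cfg$marker_taxon_prevalence[2])
    # Dirichlet draw via normalised gammas, one column per sample
    g <- matrix(stats::rgamma(n_t * n_s, shape = alpha), n_t, n_s)
    if (!is.na(marker_row)) g[marker_row, !present] <- 0
    tot <- colSums(g)
    if (any(tot == 0))
      stop("degenerate composition: a sample has zero total abundance ",
           "(marker absent and no other taxa in the panel)")
    comp <- sweep(g, 2, tot, "/")
    list(present = present, comp = comp)
  })

  dimnames(out$comp) <- list(cfg$taxa$lineage, sample_id)
  table <- taxon_abundance(out$comp, scale = "fraction")
  ann <- sample_annotation(sample_id, group)
  truth <- structure(list(
    marker_presence = stats::setNames(out$present, sample_id),
    marker_lineage = if (is.na(marker_row)) NA_character_
                     else cfg$taxa$lineage[marker_row],
    concentration = alpha
  ), class = "sim_truth")
  list(table = table, annotation = ann, truth = truth)
}
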