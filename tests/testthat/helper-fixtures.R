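# Small fixtures shared across test files; everything is generated in code.

# Tiny log2-scale protein table with a designed missingness pattern.
tiny_protein_table <- function(n_proteins = 50, n_per_group = 4, seed = 123,
                               missing_frac = 0.1, scale = "log2") {
  set.seed(seed)
  n_s <- 2 * n_per_group
  X <- matrix(rnorm(n_proteins * n_s, 20, 2), n_proteins, n_s,
              dimnames = list(sprintf("P%03d", seq_len(n_proteins)),
                              c(sprintf("PAT%02d", seq_len(n_per_group)),
                                sprintf("CTL%02d", seq_len(n_per_group)))))
  if (missing_frac > 0)
    X[sample(length(X), round(missing_frac * length(X)))] <- NA
  if (scale == "raw") X <- 2^X
  protein_groups(X, peptide_counts = rep(5L, n_proteins), scale = scale)
}

tiny_annotation <- function(n_per_group = 4) {
  sample_annotation(
    sample_id = c(sprintf("PAT%02d", seq_len(n_per_group)),
                  sprintf("CTL%02d", seq_len(n_per_group))),
    group = rep(c("patient", "control"), each = n_per_group),
    sex = rep(c("female", "male"), n_per_group),
    age = rep(60, 2 * n_per_group))
}

# Tiny taxon table with a known lineage structure.
tiny_taxon_table <- function(scale = "percent") {
  lin <- c("k__Bacteria|p__Actinobacteria|g__Cutibacterium|s__Cutibacterium_acnes",
           "k__Bacteria|p__Actinobacteria|g__Corynebacterium|s__Corynebacterium_mastitidis",
           "k__Bacteria|p__Firmicutes|g__Staphylococcus|s__Staphylococcus_aureus",
           "k__Bacteria|p__Firmicutes|g__Streptococcus|s__Streptococcus_mitis",
           "k__Bacteria|p__Proteobacteria|g__Moraxella|s__Moraxella_osloensis")
  X <- matrix(c(40, 10, 30, 15, 5,
                35, 0, 40, 20, 5,
                50, 5, 25, 15, 5,
                45, 0, 35, 10, 10), nrow = 5,
              dimnames = list(lin, paste0("S", 1:4)))
  if (scale == "fraction") X <- X / 100
  taxon_abundance(X, scale = scale)
}
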