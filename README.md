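# tearosm

Differential expression for label-free tear-fluid proteomics, with companion
summary statistics for ocular-surface microbiome (OSM) profiles.

Tear fluid can be sampled non-invasively (Schirmer strips) and its proteome
quantified by label-free LC-MS/MS, while conjunctival swabs yield taxonomic
relative-abundance profiles of the ocular surface. Case/control studies of
ocular disease — glaucoma being the motivating example — need a reproducible
downstream chain from the search engine's protein-group intensity matrix to a
volcano-ready result table, and a small set of community-level statistics for
the microbiome side. `tearosm` implements that chain as plain R with a single
fitting function and classed result objects, plus a synthetic-data module
with known ground truth so the whole pipeline can be validated end to end.

## The model

For a protein-group matrix (proteins × samples, cases vs controls) the
pipeline is:

1. **Filter**: drop protein groups with < 2 identified peptides, then
   contaminants, then groups identified in fewer than 8 samples of either
   study group, or in fewer than 9 female / 8 male samples.
2. **Normalise**: per-sample variance-stabilising calibration
   `h_s(x) = arsinh(a_s + b_s x)/ln 2`, fit by trimmed least squares against
   a median reference profile (a glog transform: ≈ `log2 x + const` at high
   intensity, linear through the additive-noise floor).
3. **Impute**: left-censored missing values drawn per sample from
   `N(μ_s − 2.5 σ_s, (0.3 σ_s)²)`, the downshifted-Gaussian convention for
   intensities missing because they fall below detectability.
4. **Test**: moderated t-test. Per-protein pooled variances `s²` (d df) are
   shrunk toward an empirical-Bayes prior: `s̃² = (d₀s₀² + d s²)/(d₀ + d)`,
   with `(d₀, s₀²)` estimated by moment matching on `log s²` and
   `t = Δ/(s̃√(1/n₁+1/n₂))` referred to `t(d₀+d)`; Benjamini–Hochberg
   adjustment follows.
5. **Call**: a fold-change-dependent significance curve. With
   `l = |log2FC|`, the adjusted-p threshold is `τ(l) = 0` for `l ≤ 1` and
   `τ(l) = 0.05·exp(−c/(l−1))` above it, `c = 0.1 ×` the SD of the log2FC
   vector: no call below a two-fold change, at most 0.05 for large changes.
6. **Stabilise**: steps 3–5 are repeated over 20 independent imputation
   cycles; proteins significant in every cycle are flagged `stable`.

Microbiome side: rank aggregation and "Under 1%" lumping of profiler-style
lineage tables, per-sample Shannon index `H = −Σ p ln p` compared by Welch's
t-test, PCA on scaled abundances, one-factor PERMANOVA
(pseudo-F from the between/within decomposition of squared distances,
add-one permutation p), and two-sided Fisher exact presence/absence tests.

## Worked example

```r
library(tearosm)

sim <- simulate_proteome(proteome_sim_config(seed = 7))   # 2250 x 32 cohort
fit <- proteome_de(sim$table, sim$annotation, seed = 7)
fit
#> Tear-proteome differential expression (moderated t, significance curve)
#>   1913 proteins tested (337 removed by filtering), 16 vs 16 samples
#>   variance prior: d0 = 2.94, s0^2 = 0.591 (df residual = 30)
#>   significant: 58 | stable over 20 imputation cycles: 57
plot(fit)                    # volcano with the significance curve
head(coef(fit))              # named log2 fold changes

simm <- simulate_microbiome(microbiome_sim_config(seed = 7))
presence_absence_test(simm$table, simm$annotation, "Corynebacterium_mastitidis")
#> presence/absence, two-sided Fisher exact test
#>   p = 0.0068
diversity_compare(simm$table, simm$annotation)
#> Shannon index, Welch t-test
#>   p = 0.934
```

The printed fit reports how many protein groups survived filtering, the
fitted variance-prior hyperparameters (`d0` small means heterogeneous
per-protein variances, large means strong shrinkage toward `s0^2`), and the
counts of curve-significant and imputation-stable proteins. The `stable`
column of `as.data.frame(fit)` is the headline call set. In this synthetic
cohort 143 of 2250 proteins carry true effects; 57 are called stable with no
false positives at this seed.

Published 2×2 tables and group summaries can be checked directly:

```r
fisher_exact_2x2(matrix(c(0, 16, 7, 9), 2, byrow = TRUE))   # 0.0068
welch_t_test(two_sample_summary(16, 16, 68.1, 76.5, 56.3, 63.2))$p  # 0.0045
```

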