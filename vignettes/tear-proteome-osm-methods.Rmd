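---
title: "Methods: tear-proteome differential expression and ocular-surface microbiome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tear-proteome differential expression and ocular-surface microbiome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tearosm)
```

# Scope

`tearosm` covers the downstream half of a two-armed ocular-surface
case/control study: from a label-free protein-group intensity matrix to a
volcano-ready differential-expression table, and from taxonomic
relative-abundance profiles to community-level summary statistics. Everything
upstream — spectral search, protein quantification, read processing,
taxonomic profiling — is out of scope; the package starts from the matrices
those tools export.

# The proteome model

## Data model and filtering

The unit of analysis is the protein group with a per-sample quantification
(MaxLFQ-style), an identified-peptide count, and a contaminant flag from the
search engine. Missingness is explicit: an empty cell means the protein was
not quantified in that sample, and for low-abundance proteins this is
missing-not-at-random — the probability of dropout rises as the true
intensity falls below detectability.

Filtering applies four rules in a fixed order, each protein charged to the
first rule that removes it: (1) fewer than 2 identified peptides
(single-peptide identifications are too unreliable to quantify); (2)
contaminant flag; (3) fewer than 8 identifications in either study group;
(4) fewer than 9 identifications among female samples or fewer than 8 among
male samples. The group/sex thresholds require each protein to be observable
in at least half of every stratum of a 16 vs 16 cohort with a 17/15 sex
split, so that group and sex effects are estimable rather than artefacts of
shared missingness. Filtering is idempotent and the per-rule removal log is
kept on the result.

## Variance-stabilising calibration

Raw-scale intensities are renormalised by a per-sample affine-arsinh
(generalised-log) transform,

$$h_s(x) = \operatorname{arsinh}(a_s + b_s x) / \ln 2, \qquad b_s > 0,$$

reported in log2 units: at high intensity $h_s(x) \approx \log_2 x + c_s$,
while through the additive-noise floor the transform is linear, which is
what stabilises the variance of low-intensity proteins. The fit alternates
two steps until the relative parameter change falls below `1e-6` (at most 50
iterations): (i) a reference profile, the per-protein median of transformed
values over well-observed proteins; (ii) per-sample least squares of the
transformed values against the reference, trimming the 10% largest squared
residuals so that genuinely differential proteins do not distort the
calibration.

Three numerical choices matter here:

* **Reference rows.** With left-censored missingness, complete cases are few
  and biased toward high intensity. The reference uses complete cases when
  at least 30 exist and otherwise proteins observed in ≥ 75% of samples
  (medians over observed cells).
* **Gauge fixing.** The alternation has a two-dimensional degenerate family:
  a common rescaling $(a, b) \to c(a, b)$ and a common offset
  $a \to a + e$ change every sample identically, so cross-sample residuals
  cannot see them — but they can drive the fit toward maximally compressive
  transforms (all samples flat, reference flat, residuals "perfect"). Both
  modes are pinned after every iteration: geometric-mean slope ratio to the
  initial calibration held at 1, mean offset held at 0. The initial slope
  places the glog transition at each sample's 2% intensity quantile, i.e.
  the bulk of the data in the logarithmic regime.
* **Trim-set freezing.** Borderline proteins flipping in and out of the
  trimmed 10% can hold the alternation in a limit cycle; trim sets adapt for
  15 burn-in iterations and are then frozen. Each per-sample fit solves the
  linear problem $a + b x \approx \sinh(\text{ref})$ (exact when a sample
  truly is an affine distortion of the reference) with least-trimmed-squares
  concentration steps, and a Nelder-Mead refinement of the trimmed objective
  on the arsinh scale runs once at the end.

Non-convergence yields the best iterate with a warning. The transform is
strictly increasing, so within-sample ranks are always preserved. Log2-scale
input is accepted as already calibrated and passes through unchanged.

## Downshifted-Gaussian imputation

Missing cells in sample $s$ are drawn independently from
$N(\mu_s - 2.5\,\sigma_s,\ (0.3\,\sigma_s)^2)$, where $\mu_s, \sigma_s$ are
the mean and SD of the sample's *observed* log2 intensities. This is the
standard left-censored imputation: absent proteins are assumed to sit below
the detection limit, so values are placed in the lower tail of the sample's
distribution, narrowed so imputed values do not dominate the variance.
Width 0.3 and downshift 2.5 (both in per-sample SD units) are the
conventional defaults and are exposed in `imputation_config()`. "Sample
standard deviation" is resolved as per-sample statistics over the observed
protein-group intensities — imputation operates on the protein-group
matrix, not on peptides. Observed cells are never modified; a sample needs
at least 2 observed values.

## Moderated t-test

Per protein, the two-group model gives `log2fc` (cases − controls) and a
pooled residual variance $s^2$ on $d = n_1 + n_2 - 2$ df. Variances are
assumed exchangeable across proteins with a scaled-inverse-chi-squared
prior $(d_0, s_0^2)$; the posterior variance
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$ gains $d_0$ df, and the
moderated $t = \Delta / (\tilde s \sqrt{1/n_1 + 1/n_2})$ is referred to
$t(d_0 + d)$.

Hyperparameters are estimated by moment matching on
$e = \log s^2 - \psi(d/2) + \log(d/2)$, which has variance
$\psi'(d/2) + \psi'(d_0/2)$ under the model: solve
$\psi'(d_0/2) = \operatorname{var}(e) - \psi'(d/2)$ by a Newton iteration on
the trigamma inverse, then
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. When the observed
spread of log variances does not exceed pure chi-squared sampling noise the
equation has no finite root and $d_0 = \infty$ is returned — every protein
is then tested at the common variance $s_0^2 = \exp(\bar e)$ with normal
reference. Zero-variance proteins are excluded from estimation (with a
warning); `d0 = 0` disables moderation and reproduces the ordinary pooled
t-test exactly, which the tests exploit as an oracle. The test suite also
cross-checks the whole fit against `limma::eBayes` — agreement is close but
not identical, since limma's hyperparameter estimator applies a small-sample
bias correction this moment-matching estimator omits.

## Significance curve and stability flags

Benjamini-Hochberg adjustment (step-up, implemented explicitly and tested
against `stats::p.adjust`) is followed by a fold-change-coupled threshold.
With $l = |\text{log2fc}|$:

$$\tau(l) = \begin{cases} 0 & l \le 1 \\ 0.05\, e^{-c/(l-1)} & l > 1,\end{cases}
\qquad c = 0.1 \times \hat\sigma,$$

and a protein is significant iff $p_{\text{adj}} \le \tau(l)$. The curve's
contract is: no call at or below a two-fold change, a threshold rising
continuously and strictly with fold change, and supremum 0.05 at large fold
changes. The exponential form is the simplest satisfying all three; it is a
deliberate design choice (the requirements pin the asymptotes, not the
functional form) and is recorded in the run report. The "overall standard
deviation" entering $c$ is resolved as the SD of the log2 fold-change
vector; `sd_reference = "intensity_sd"` preserves the alternative reading
(SD of all log2 intensities). The literal threshold-function reading is
implemented, not a SAM-style fudged statistic.

Imputation noise can flip borderline calls, so the impute → test → adjust →
call cycle is repeated `n_cycles = 20` times with sub-seeds derived from the
global seed by a fixed splitting rule. BH and the curve are recomputed
within each cycle (each cycle is a complete analysis; this makes stability
meaningful). Cycle 1 is the reference reported in the result table, and
`stable` flags proteins significant in **all** cycles — by construction a
subset of the reference significant set. Per-cycle calls are retained as a
diagnostics attribute.

# The microbiome statistics

Taxon tables carry profiler-style lineage strings
(`k__...|p__...|g__...|s__...`) and per-sample relative abundances (percent
or fraction, recorded). Aggregation sums within a rank label and conserves
per-sample totals to 1e-9; "Under 1%" lumping removes taxa whose *group
mean* abundance is below 1% in every comparison group and reports their
per-sample sum as one row. The group-mean rule (rather than per-sample or
overall-mean) is chosen so that a taxon plentiful in one group cannot be
lumped away by its absence in the other; the overall-mean variant is
available by flag.

Diversity uses the Shannon index $H = -\sum p_i \ln p_i$ (natural log, the
ecology default; the base is a convention, not an inference choice) on
renormalised nonzero components, compared between groups by Welch's t-test.
Community comparison scales each taxon to zero mean and unit variance,
runs an SVD-based PCA (deterministic sign convention: the
largest-magnitude loading of each component is positive), and tests group
separation by one-factor PERMANOVA on Euclidean distances of the same
scaled matrix — so ordination and test view identical geometry; Bray-Curtis
on the untransformed compositions is available as an option. The PERMANOVA
p-value uses the add-one rule $p = (\#\{F^* \ge F\} + 1)/(n_{perm}+1)$, so
it can never be zero and its floor is $1/(n_{perm}+1)$; 1000 permutations by
default.

Presence/absence association of a named taxon uses a two-sided Fisher exact
test by full hypergeometric enumeration with the probability-mass rule
(tables no more probable than the observed one, relative tie tolerance
1e-7 — the common software default when only "two-tailed" is specified).
The detection threshold for "positive" is any nonzero abundance, which
makes the call invariant to percent-vs-fraction scaling. Degenerate margins
return $p = 1$.

The chi-squared helper implements the plain Pearson statistic and the
Yates-corrected variant. Published sex-ratio statistics are often not
reproducible from printed marginal counts because the variant (or software)
is rarely stated; both variants are exposed and documented rather than
guessing at a third.

# The synthetic-data module

`simulate_proteome()` generates complete log2 intensities
$x_{gs} = \beta_g + \delta_g\,[s \in \text{cases}] + \varepsilon_{gs}$ with
per-protein baselines $\beta_g \sim N(20, 2.5^2)$ (log2 units, the scale of
typical LFQ output), effects $\delta_g \sim N(0, 1.5^2)$ for a differential
fraction of 123/2250 ≈ 5.5% (the observed differential fraction in tear
cohorts of this design) and 0 otherwise, and within-protein variances drawn
scaled-inverse-chi-squared $(d_0 = 4,\ s_0^2 = 0.25)$ — the same family the
moderated test assumes, so hyperparameter recovery is a meaningful
validation. Missingness is then imposed by logistic left-censoring:
cell missing with probability $1/(1 + e^{b(x - m)})$, midpoint $m = 16$
(about 1.6 between-protein SDs below the baseline mean, giving ~10–12%
missingness concentrated in low-abundance proteins) and slope
$b = 0.8$ per log2 unit. The logistic mechanism is a modelling choice: the
downshift imputation it feeds presumes intensity-dependent dropout, but no
particular dropout law. The cohort mirrors the motivating design: 16
patients (7 F / 9 M) vs 16 controls (10 F / 6 M), ages
$N(76.5, 7.7^2)$ / $N(68.1, 7.3^2)$ years. Peptide counts (5% single-peptide)
and contaminant flags (2%) exist to exercise the filter.

`simulate_microbiome()` draws per-sample Dirichlet compositions over a
12-species, 4-phylum panel whose concentrations mirror typical
ocular-surface dominance (Cutibacterium acnes, Limosilactobacillus
fermentum, Staphylococcus aureus leading), with one marker species —
Corynebacterium mastitidis — present with group-specific probability
(default 0 in patients, 7/16 in controls) and structurally zero otherwise;
compositions are renormalised to sum to one.

What the simulators do **not** emulate: correlated proteins or taxa
(co-expression blocks, compositional correlation beyond the closure),
batch/run-order effects, peptide-level structure, sequencing noise,
zero-inflation beyond the marker mechanism, or age/sex effects on the
measurements themselves. Passing tests therefore demonstrate that the
chain is implemented correctly and calibrated under its own assumptions —
not that those assumptions hold for any particular real dataset.

Determinism: every stochastic operation takes its randomness from a
sub-seed derived from one global integer seed by a fixed multiplicative
splitting rule (`split_seed()`), and identical config + seed reproduces
every output bit for bit.

# Validation strategy and problem sizes

The test suite pairs each statistic with an independent oracle
(`stats::fisher.test`, `stats::p.adjust`, `stats::prcomp`,
`vegan::adonis2`, `vegan::diversity`, `limma::eBayes`, hand-evaluated
closed forms) — the implementations never delegate to these. Calibration
checks use 200-replicate exchangeable nulls (fraction of p ≤ 0.05 inside
the binomial 99% band), null false-call rates use five 2000-protein
cohorts, effect recovery uses a 2250-protein cohort with 10% true effects,
and hyperparameter recovery uses 5000 null proteins; these sizes give
stable Monte-Carlo behaviour at interactive runtimes. `scripts/acceptance.R`
recomputes the same headline quantities from a single command-line seed.

# Known limitations

* The calibration is a trimmed-least-squares approximation to full
  robust-ML variance stabilisation; its contract (affine recovery, rank
  preservation, variance stabilisation) is tested, numeric identity with
  other implementations is not claimed.
* The moderated-t hyperparameter estimator omits small-sample bias
  corrections; with thousands of proteins the difference is negligible.
* PERMANOVA is one-factor only, with no covariate adjustment; associations
  confounded with age or medication need a dedicated modelling tool.
* The significance curve's exponential form is one of many satisfying the
  stated asymptotics; conclusions near the curve should be read together
  with the stability flag, which is exactly what it is for.
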