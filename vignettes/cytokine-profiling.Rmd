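---
title: "Latent-variable profiling of cytokine panels: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable profiling of cytokine panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiplex bead immunoassays report the concentrations of 20-40 cytokines
and chemokines per tissue sample. In studies of interacting pathologies
(for instance amyloid plus diabetic models crossed into one mouse), the
scientific question is rarely about a single cytokine: it is whether a
*profile* - a weighted combination of analytes - distinguishes a combined
pathology from each single pathology, and whether that profile tracks
peripheral phenotypes such as plasma glucose, insulin, or amyloid-beta.
`cytolv` implements that analysis as a tested, scriptable pipeline:

1. normalization to total protein and detection-limit handling,
2. per-analyte z-scoring within the sample set of each comparison,
3. partial least squares (PLSDA for group designs, PLSR for continuous
   phenotypes) fitted by NIPALS,
4. an orthogonal rotation of the first two latent variables toward an
   explicit separation objective,
5. Monte-Carlo subsampling with sign correction to put error bars on the
   per-analyte profile,
6. Welch ANOVA with Dunnett T3 pairwise comparisons (or Pearson
   correlation) on the composite scores.

## The model

With $X$ the $n \times p$ z-scored panel and $Y$ the centered response
(indicator columns for groups, or a centered phenotype), NIPALS extracts
components $a = 1, 2, \dots$: a unit-norm weight vector $w_a$, scores
$t_a = X_{a-1} w_a$, X-loadings $p_a = X_{a-1}^\top t_a / t_a^\top t_a$,
and deflation $X_a = X_{a-1} - t_a p_a^\top$. $Y$ is not deflated (the
common PLS2 convention). The inner loop starts from the $Y$ column of
largest variance, so fits are deterministic. For one component the weight
equals the dominant left singular vector of $X^\top Y$; this identity is
the oracle used by the test suite. Exactly two components are used
throughout the pipeline (the core supports more); note that SIMPLS or
Y-deflating variants can differ from component 2 onward.

### Rotation of the LV1-LV2 plane

PLS orders components by response covariance, not by how cleanly the
contrast of interest separates. The pipeline therefore rotates the
$(w_1, w_2)$ pair within its plane: for angles $\theta$ on a uniform grid
over $[0, \pi)$ (default 3601 points, i.e. 0.05 degrees), the rotated
score $t(\theta) = \cos\theta\, t_1 + \sin\theta\, t_2$ is evaluated under
one of three objectives:

* **contrast_separation** (default for combined-vs-each-alone designs):
  mean score of a designated group minus the pooled mean of the rest;
* **group_F**: omnibus Welch F across all groups;
* **phenotype_correlation** (PLSR): $|r|$ against the phenotype.

Angles $\theta + \pi$ are sign flips, handled separately as orientation:
the designated group (or positive phenotype association) always ends up
scoring positive on rotated LV1. A grid search was chosen over closed-form
optimization because the Welch-F objective is cheap but not smooth in
closed form; the grid is exhaustively checked against a 10x finer
brute-force scan in the acceptance suite. Because all three objectives
reduce to per-group first and second moments of $(t_1, t_2)$, the whole
grid is evaluated vectorized, which is what makes rotation affordable
inside every subsample refit.

The input weight pair from NIPALS is orthogonal in exact arithmetic;
`rotate_lv_plane()` performs one Gram-Schmidt pass to strip the ~1e-16
floating-point drift (the span is preserved to the same order), so the
rotated pair satisfies $|w_1 \cdot w_2| \le 10^{-15}$ at *every* grid
angle - the bound `check_orthogonality()` enforces before any scores are
used for ANOVA. A pair violating orthogonality by more than 1e-8 on input
is treated as a contract error, not silently repaired.

### Subsampling stability

Error bars on the per-analyte profile come from model regeneration: for
each of 1000 iterations (default), draw a stratified 80% subsample of each
group without replacement (at least 2 per group), re-z-score within the
subsample, refit, re-rotate with the same objective, then align the
refitted LV with the full-model LV by multiplying with the sign of their
scalar product. The mean and SD over iterations per analyte form the bar
plot with error bars. Two deliberate choices here:

* each subsample is re-standardized before refitting, because the pipeline
  defines standardization as part of the fit;
* the rotation is re-optimized per subsample by default (rotation is part
  of "model regeneration"); `reoptimize_rotation = FALSE` reuses the
  full-model angle instead.

A master seed derives one substream seed per iteration, so any single
iteration is reproducible in isolation. Degenerate subsamples (a
zero-variance analyte, a collapsed group) are resampled and logged, with a
hard error after 100 consecutive failures.

## Statistics on composite scores

Group comparisons on LV scores use Welch's heteroscedastic ANOVA
($F^*$ with weights $n_g/s_g^2$ and Satterthwaite-type denominator df)
followed by Dunnett T3 pairwise tests: per-pair Welch $t$ with
Welch-Satterthwaite df. The exact T3 reference distribution is the
studentized maximum modulus; under independence with per-pair df that
probability *is* the Sidak bound $1-(1-p)^m$, $m = k(k-1)/2$, which is
what the package computes. Because the pairwise statistics share group
means (positive dependence), the bound is conservative; simulated
family-wise error at $n = 7/7/7$ is ~3.5% at a nominal 5% (checked at
10,000 replicates in the acceptance suite). No separate "exact SMM"
code path exists, since it would reduce to the same computation.

Phenotype association uses Pearson's $r$ with the $t$ transform
$r\sqrt{(n-2)/(1-r^2)}$.

### Outlier removal

Univariate statistics can optionally drop outliers per analyte per group
with a one-sample ROUT-style procedure: residuals from the median, robust
scale RSDR = 68.27th percentile of absolute residuals times $n/(n-1)$,
t-like statistics tested most-extreme-first against the
Benjamini-Hochberg step-down thresholds $Q\,i/n$ (df $= n-1$), stopping at
the first non-significant point. At $Q = 0.01$, $n = 8$, the measured
false-positive rate on clean normal samples is ~1%, and a contaminant
sitting 10 robust SDs from the robust center is essentially always caught.
The regression form of ROUT is out of scope; multivariate fits always use
all samples, so outlier removal only ever affects univariate tables.

### A caution on circularity

Rotating LV1 to maximize a separation objective and then testing that same
separation with ANOVA on the same samples is circular: under a true null
the omnibus p-values on rotated LV1 are stochastically smaller than
uniform. The original analysis style does this without correction; the
pipeline reports it the same way but records a warning in every run
manifest. Interpret rotated-score p-values as descriptive strength of the
(optimized) separation, not as calibrated hypothesis tests; the
subsampling profile SDs, not the ANOVA stars, are the stability evidence.

## The synthetic world

No real cohort ships with the package (the motivating kind of dataset is
typically available only on request), so validation rests on a generator
with known truth:

* **Marginals**: log-normal concentrations - immunoassay data are positive
  and right-skewed. Baseline log-means span roughly 5-90 pg/mg across the
  22-analyte default panel; log-SD 0.5 everywhere, a realistic biological
  coefficient of variation of ~50%.
* **Effects**: additive shifts on the log scale per group, plus an
  *interaction* shift applied only to the designated combined-pathology
  group - the cooperative-upregulation structure the analysis is meant to
  detect. Preset scenarios put the interaction (+1.2 log-units) on five
  chemokine-type analytes and moderate main effects (+0.3 amyloid-like,
  +0.5 diabetes-like) on broader sets; the acceptance recovery experiment
  uses +1.5 on five designated analytes with no main effects.
* **Noise correlation**: compound symmetry with $\rho = 0.3$ across
  analytes (cytokines are co-regulated; an exchangeable structure is the
  simplest defensible emulation).
* **Censoring**: per-analyte detection limits; preset scenarios include a
  G-CSF analyte whose LOD censors it in the majority of samples, so the
  exclusion rule (drop analytes censored in > 50% of samples, impute
  surviving censored cells at LOD/2 by default) is exercised end-to-end.
* **Phenotypes**: each is intercept + slope x latent inflammation factor +
  Gaussian noise, where the latent factor of a sample is its mean injected
  log shift across affected analytes. Couplings follow the metabolic sign
  structure (glucose positive, insulin negative in the T2D-like scenario,
  plasma amyloid negative).
* **Design**: three groups of 7, mirroring typical cohort sizes in this
  literature (21 mice per comparison).

What a green test does *not* establish: the generator has no plate
effects, no inter-assay drift, no sex-stratified effects (sex is metadata
only), Gaussian log-noise rather than heavy-tailed contamination, and
group-wise homoscedasticity on the log scale. Effect sizes in real mice
are unknowable from z-scored heatmaps, so presets are qualitative
emulations, not calibrations.

## Numerical choices

* z-scoring uses the sample SD (denominator $n-1$) and is recomputed
  within the sample subset of each analysis; zero-variance analytes are a
  named error for the caller to drop.
* NIPALS converges each weight vector to 1e-12 (max 500 iterations);
  non-convergence is an error carrying the component index; an exhausted
  X residual (rank deficiency) stops early with a warning.
* Detection limits are stored per cell so per-sample protein normalization
  transforms them identically with the values.
* Sub-LOD cells of retained analytes are imputed at LOD/2 by default
  (config: LOD/2, LOD, or missing) - the upstream convention in
  immunoassay work; the source analyses do not state their choice.
* The rotation orientation rule breaks the $\theta$ vs $\theta + \pi$ tie;
  within the grid, ties in the objective resolve to the smallest angle
  (`which.max`).
* Default protein normalization: 50 uL of lysate at 7.5 ug/uL per well,
  i.e. 0.375 mg.

## Known limitations

* The PLS variant is NIPALS PLS2 with X-only deflation; other variants
  (SIMPLS, Y-deflating NIPALS) agree on component 1 (the SVD identity)
  but can differ beyond it. Equivalence with any specific legacy
  implementation is claimed only for component 1.
* Dunnett T3 p-values use the Sidak bound (conservative).
* The rotation objective of the original analyses ("better separated
  groups") was never formalized; both candidate objectives are
  implemented, neither is asserted to be the original.
* ROUT is the one-group location case only.
* No cross-validated component selection, VIP scores, permutation nulls,
  or bootstrap-with-replacement variants.
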