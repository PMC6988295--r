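# cytolv

Latent-variable profiling of multiplex cytokine panels.

## What problem this solves

Bead-based multiplex immunoassays (Luminex-type) measure 20+ cytokines
and chemokines per tissue sample. In cohort designs where two pathologies
are combined (e.g. an amyloid mouse model crossed with a diabetic model),
the question is whether a *profile* of cytokines — a weighted combination
of analytes — distinguishes the combined pathology from each single
pathology, and whether that profile tracks peripheral phenotypes (plasma
glucose, insulin, amyloid-beta). `cytolv` is a tested R implementation of
that workflow for biostatisticians and neuroinflammation labs:

- panel I/O, total-protein normalization (pg/mL → pg/mg), detection-limit
  exclusion and imputation, per-analyte z-scoring;
- PLSDA / PLSR fitted from scratch by NIPALS (deterministic, X-deflating
  PLS2), scores `T = X W` with unit-norm weight columns;
- an orthogonal rotation of the LV1–LV2 plane that picks the angle
  maximizing an explicit separation objective (group contrast, omnibus
  Welch F, or phenotype correlation), with the rotated pair guaranteed
  orthogonal to `|w1·w2| ≤ 1e-15`;
- Monte-Carlo subsampling (default 80% of samples, 1000 iterations,
  without replacement) with sign correction
  `w ← w · sign(w·w_ref)` to put mean ± SD error bars on each analyte's
  LV weight;
- Welch ANOVA with Dunnett T3 pairwise tests on composite LV scores,
  Pearson correlation against phenotypes, ROUT-style robust outlier
  removal for univariate tables;
- a synthetic cytokine-panel generator with known ground truth (log-normal
  marginals, correlated noise, cooperative interaction effects, censored
  analytes, coupled phenotypes) used by the test suite for end-to-end
  recovery experiments.

## Worked example

Simulate a type-2-diabetes-like scenario (three groups of 7: amyloid-only,
db/db-only, combined; a +1.2 log-unit cooperative interaction on five
chemokines) and run the discriminant pipeline:

```r
library(cytolv)

truth <- preset_scenarios("dbdb_like")
gen <- generate_panel(truth, seed = 7)

cfg <- run_config(gen$panel, mode = "plsda",
                  positive_group = "APP_PS1-db-db",
                  iterations = 1000, seed = 42)
res <- run_plsda(cfg)

res$rotation
#> <rotation_result> theta = 2.9305 rad, objective contrast_separation = 4.22
res$anova_lv1
#> Welch ANOVA: F(2, 11.02) = 71.0552, p = 5.059e-07 ***
#>   APP_PS1 vs db-db: t = -0.538, df = 11.97, p_adj = 0.9361 ns
#>   APP_PS1 vs APP_PS1-db-db: t = -12.096, df = 7.26, p_adj = 1.345e-05 ***
#>   db-db vs APP_PS1-db-db: t = -11.792, df = 7.40, p_adj = 1.388e-05 ***

head(as.data.frame(res$profiles$lv1)[order(-res$profiles$lv1$mean_signal), ], 6)
#>    analyte mean_signal sd_signal
#> 20  MIP-1b       0.432   0.01339
#> 18   MCP-1       0.429   0.01015
#> 16   IFN-g       0.410   0.01417
#> 19  MIP-1a       0.409   0.00786
#> 15  GM-CSF       0.387   0.01944
#> 2    IL-1b       0.200   0.03870
```

Reading this: the rotated LV1 separates the combined group (oriented
positive) from both single pathologies — the omnibus Welch ANOVA and both
Dunnett T3 comparisons against the combined group are significant, while
the two single pathologies do not differ from each other. The profile
table recovers exactly the five analytes that carry the injected
interaction (MIP-1b, MCP-1, IFN-g, MIP-1a, GM-CSF) as the top LV1
weights, with subsampling SDs an order of magnitude below the means.
G-CSF, censored in most samples by construction, is excluded upstream and
reported in `res$exclusions`.

Regressing the panel on a phenotype instead (PLSR mode):

```r
cfg2 <- run_config(gen$panel, mode = "plsr", phenotype = "glucose",
                   iterations = 200, seed = 42)
run_plsr(cfg2)$correlation
#> Pearson r = 0.901 (n = 21), p = 2.456e-08 ***
```

Note the caveat that applies to both modes: LV1 is *rotated to maximize*
the reported separation/correlation before it is tested, so these
p-values are descriptive, not calibrated null tests (every run manifest
records this).

## Command line

```sh
./exec/cytolv simulate --scenario dbdb_like --seed 7 --out sim/
./exec/cytolv plsda --panel sim/panel.csv --meta sim/metadata.csv \
    --contrast APP_PS1-db-db --iterations 1000 --seed 42 --out run/
./exec/cytolv plsr  --panel sim/panel.csv --meta sim/metadata.csv \
    --phenotype glucose --seed 42 --out run_glucose/
```

Outputs per run: `lv1_profile.csv` / `lv2_profile.csv` (per-analyte
mean ± SD, ordered by descending LV1 signal), `scores.csv`, `anova.csv`
and `pairwise.csv` (with `*`/`**`/`***` at 0.05/0.01/0.001),
`zscores.csv` (the standardized matrix), a `model/` bundle (W/P/Q/T CSVs
plus `model.json`), `exclusions.json`, and `manifest.json` (seed, config
hash, rotation angle, versions). Flags can be supplied via `--config file.json` (or `.yaml` if
the `yaml` package is installed); explicit flags win.

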