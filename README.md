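# dexmet

Analysis of repeated-measures plasma metabolome time courses with a
mid-study treatment intervention — the design of a single-dose
glucocorticoid (dexamethasone) study: 20 subjects sampled morning /
midday / evening over four days, dosed after midday of day 3, giving
seven untreated and four post-dose sampling slots (+6, +18, +24, +30 h)
per subject and 220 samples of ~214 metabolites.

For metabolomics analysts working with such designs, the package
provides the full pipeline:

* **Preprocessing** — normalization to pooled-reference medians, log10
  transform, autoscaling (center + unit variance, n−1 SD).
* **Univariate stage** — per metabolite, a time-matched random-intercept
  ANOVA `log10(y) ~ treatment + age + BMI + (1 | subject)` (REML via
  nlme), Wald t and p, Benjamini–Hochberg q-values, linear-scale fold
  changes (group mean / reference mean), a pre-check that replicate
  untreated slots differ only at the false-positive rate
  (0.05 × 214 ≈ 11 metabolites), circadian contrasts, and deregulation
  counts.
* **STATIS** — a from-scratch multi-table ordination: per-subject
  time-point cross-products W_k = X_k X_kᵀ/M, RV-coefficient
  interstructure C, subject weights α = leading eigenvector of C (unit
  Euclidean norm; 1/√K = 0.224 for K = 20 identical tables), compromise
  W = Σ α_k W_k, eigendecomposition, and projection of time points,
  subject trajectories and metabolites.
* **PLS-DA** — NIPALS PLS1 of treated vs untreated with
  leave-one-subject-out cross-validated Q²,
  Q²cum(A) = 1 − Π (PRESS_a / SS_{a−1}).
* **Metabolic phenotypes** — pairwise Kendall tau-b of subject rankings
  across time points; a metabolite is a stable phenotype constituent
  when mean(τ) − SD(τ) ≥ 0.6.
* **Synthetic cohorts** — a seeded generator with circadian monotone
  trends, stable subject offsets, post-dose effect profiles and pooled
  reference samples, supplying ground truth for every stage.

## Worked example

```r
library(dexmet)

spec <- study_cohort_spec(seed = 1)   # study-emulating synthetic cohort
m    <- generate_cohort(spec)
p    <- autoscale(log10_transform(normalize_to_pool(m)))

# univariate: time-matched treatment effects
res <- treatment_anova(p, covariates = FALSE)
count_deregulated(res, q_threshold = 0.05)$any_slot
#> [1] 153

# STATIS ordination
statis(p)
#> statis_model: 20 subject tables, 11 time points
#>   weights: 0.222 - 0.224 (equal-weight value 0.224 )
#>   explained variance: axis1 44.4% axis2 11.8%

# PLS-DA with leave-one-subject-out Q2
plsda_treated(p)$cv$q2_cum
#> [1] 0.9625454 0.9711989

# stable metabolic phenotypes
sum(stability_scores(m)$selected)
#> [1] 24
```

153 of 214 metabolites are deregulated (q < 0.05) at one or more
post-dose slots — close to the 150 planted in this cohort. The STATIS
weights sit tightly around the equal-weight value 0.224, as expected
for a homogeneous simulated cohort. Q²cum(2) = 0.97 reflects the strong
planted treatment separation, and 24 of the 27 planted phenotype
metabolites pass the rank-stability rule.

The whole pipeline, with CSV outputs and an md5 manifest, runs as

```r
summary <- run_pipeline(list(out_dir = "results", seed = 1))
```

or from a shell via the thin wrapper
`Rscript inst/scripts/dexmet.R --config run.yaml --out results`.

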