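---
title: "Analysing treatment time-course metabolomes with dexmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing treatment time-course metabolomes with dexmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A classic design in clinical metabolomics samples the same individuals
repeatedly over several days, administers a drug mid-study, and asks
three questions at once: what does the drug do to the metabolome, what
does the time of day do, and which metabolite levels are properties of
the individual rather than of the moment? dexmet implements a complete
analysis for this design, built around the schedule of a single-dose
glucocorticoid study: 20 subjects, three fixed sampling times per day
(morning, midday, evening) over four days, with the dose taken after
midday of day 3. That yields seven untreated slots and four post-dose
slots (+6, +18, +24, +30 h); day 1 has no morning sample, so a full
cohort is 220 study samples.

The repeated-measures structure matters everywhere. Samples from one
person are correlated (their metabolome is individual), and metabolite
levels drift with the time of day, so every statistical decision below
either models the subject explicitly (random intercepts, subject-wise
cross-validation, per-subject data tables) or conditions on the day
time (time-matched contrasts).

```{r, eval = FALSE}
library(dexmet)
summary <- run_pipeline(list(out_dir = "results", seed = 1))
summary
```

## Preprocessing

Raw MS intensities carry instrumental variation, so every metabolite is
first divided by the median of the pooled reference samples — repeated
injections of an aliquot pool of all study samples. The operation is
invariant to any global rescaling of the run. Values are then
log10-transformed (multiplicative biology becomes additive, closer to
normal), and for multivariate work each metabolite is centered and
scaled to unit variance ("autoscaling", n−1 denominator, parameters
estimated once on all 220 samples jointly and stored so held-out data
can be projected). Without autoscaling the handful of highest-variance
metabolites would dominate every ordination. Batch-wise pool
normalization is out of scope: the generator does not simulate batch
structure, and the normalization stage is validated on synthetic pools
only.

## Univariate stage: time-matched mixed-effects ANOVA

Because roughly half the metabolome is circadian, a post-dose evening
sample may differ from an untreated morning sample for reasons that
have nothing to do with the drug. Treatment effects are therefore only
ever tested against untreated slots at the *same* day time, and the
untreated replicate days are pooled (day 1 + day 2 evenings, etc.).
The pooling is justified empirically per data set by
`precheck_combination()`: between two untreated slots of the same day
time, the number of metabolites with p < 0.05 (paired t across
subjects) should be near the nominal false-positive count, 0.05 × 214
≈ 11.

Per metabolite and comparison, the model is

log10(y) = β0 + β1·group + β2·age + β3·BMI + u_subject + ε,

a random-intercept mixed model fitted by REML (`nlme::lme`, the
standard R machinery for this model class), with the Wald t and its
two-sided p-value reported for the group indicator. We deliberately fit
one model per comparison rather than one joint model over all 11 slots:
the time-matched contrast is the scientific question, and a joint model
would pool residual variance across day times with different biology.
Singular fits (possible at degenerate noise levels) fall back to OLS
and are flagged `ols_fallback`, never dropped. p-values are converted
to q-values by Benjamini–Hochberg within each comparison; the standard
thresholds are q < 0.05 for treatment and circadian screens and
q < 0.1 for the age/BMI covariate screen.

Fold changes are reported as the arithmetic mean of linear-scale values
in the group divided by the reference mean — not the back-transformed
difference of log means. The two disagree under skew; the linear-scale
ratio is the convention the downstream read-outs (e.g. "dropped to 16%
of morning levels") assume.

## STATIS: a compromise ordination across subjects

PCA of such data is dominated by inter-individual differences, which
obscure the treatment. STATIS integrates one table per subject — the
11 × 214 autoscaled time-course — into a consensus:

1. Per subject k, the time-point cross-product matrix
   W_k = X_k X_kᵀ / M (11 × 11): how similar the subject's metabolic
   state is at any two time points. Dividing by the metabolite count M
   keeps the scale independent of panel size.
2. The interstructure C with C_ij = ⟨W_i, W_j⟩_F / (‖W_i‖_F ‖W_j‖_F),
   the RV coefficient — a matrix analogue of squared correlation.
3. Weights α = the leading eigenvector of C, sign-fixed non-negative
   (Perron–Frobenius guarantees existence) and normalized to unit
   Euclidean norm. Subjects similar to everyone get high weight;
   outliers are down-weighted. With K identical tables every weight is
   1/√K — 0.224 at K = 20 — which is why observed weights cluster
   around that value for homogeneous cohorts. We chose the unit-norm
   convention over sum-to-one because only the former puts equal
   weights at a magnitude comparable to reported per-subject weights
   in the 0.17–0.26 range; sum-to-one would give 0.05.
4. The compromise W = Σ α_k W_k and its eigendecomposition: time-point
   scores U·diag(√λ), per-subject trajectories W_k u_a/√λ_a (whose
   α-weighted average reproduces the compromise scores exactly — an
   identity tested to 1e-8), and metabolite loadings from projecting
   the α-weighted average table. Tiny negative eigenvalues (roundoff)
   are clipped at zero; a genuinely indefinite compromise (min λ <
   −1e-8·max λ) is an error. Each eigenvector's largest-magnitude
   entry is made positive so output is deterministic.

Cross-products are computed on globally autoscaled data without
additional per-subject centering; the convention is recorded in the
provenance, and on synthetic tests the centered variant gives the same
rankings.

## PLS-DA and leave-one-subject-out Q²

The supervised counterpart regresses a centered 0/1 treated indicator
on the autoscaled data (PLS1, NIPALS — deterministic, no iteration for
a univariate response). Model quality is judged by cross-validated Q²,
with folds defined by *subject*: all 11 samples of one individual are
held out together, because sample-wise CV would let a subject's other
samples leak into training and flatter the model. Per component,
Q²_a = 1 − PRESS_a/SS_{a−1}, where SS_{a−1} is the y residual sum of
squares after a−1 components of the all-data fit, and cumulatively
Q²cum(A) = 1 − Π_a (PRESS_a/SS_{a−1}) — the convention of mainstream
chemometrics software, whose exact internal bookkeeping is proprietary;
we therefore also report the plain 1 − PRESS_A/SS_0 and declare the
convention in the output rather than claim bit-level agreement. Folds
whose training data collapse to a single class are skipped with a
warning. Class imbalance (140 untreated vs 80 treated samples in the
default design) is left unweighted.

## Metabolic phenotypes via Kendall rank stability

A metabolite is a phenotype constituent if the *ranking of subjects* is
preserved across time. For each metabolite, Kendall's tau-b is computed
over subjects for every unordered pair of untreated slots (21 pairs for
7 slots), and the metabolite is selected when
mean(τ) − SD(τ) ≥ 0.6 (SD with n−1 across the pairs; the inequality is
exactly ≥). tau-b's tie correction rarely matters for continuous data
— tau-a agrees almost surely — but is used for reproducibility. Because
tau is invariant under strictly monotone transforms, it is immaterial
whether raw, pool-normalized or log values enter; selection is also
checked with the four post-dose slots included (55 pairs), since a
treatment that shifts all subjects equally leaves rankings — and
therefore tau — untouched, while subject-specific responses lower it.

## The synthetic-cohort generator

Real measured values for this design live in a study supplement without
a public accession, so validation runs on synthetic cohorts whose
generative model mirrors the analysis assumptions — log10-additive,
hence multiplicative on the linear scale:

log10(y_ijt) = μ_j + b_ij + c_j(daytime) + d_j(hours post-dose) + ε.

The study-emulating defaults (`study_cohort_spec()`) were fixed once:
20 subjects × 11 slots, 214 metabolites; baselines μ_j ~ N(2, 0.5);
circadian increments of |U(0.04, 0.12)| log10 units per half-day for 78
rising and 25 falling metabolites (monotone within day, identical
across days — which is exactly what justifies pooling replicate
untreated slots); post-dose effects of |log10 effect| ~ U(0.1, 0.4) on
150 metabolites, 9 of them at all four offsets; 27 phenotype
metabolites with subject SD 0.35 against residual SD 0.1 (ratio 3.5;
other metabolites 0.1/0.1); ages N(25.5, 2.9²) and BMI N(23.3, 2.7²)
truncated to plausible adult ranges, with zero effect on metabolites by
default. Ten pool replicates are generated as per-metabolite means of
all study samples with noise_sd/4 multiplicative noise; pool frequency
is unpublished for the motivating design, so ten is a pragmatic choice
that exercises the normalization.

What the generator does *not* emulate: instrument drift and batch
order, missingness, heavy-tailed measurement error, non-monotone
within-day kinetics, and covariate effects on metabolites. Passing
tests therefore demonstrate that the *statistical machinery* is
correct under its own assumptions — recovery of planted effects,
nominal error control, algebraic identities — not that real plasma
data meet those assumptions.

At the chosen phenotype spread (ratio 3.5), expected pairwise tau is
(2/π)·arcsin(0.35²/(0.35²+0.1²)) ≈ 0.75, and the mean−SD ≥ 0.6 rule
recovers ~93% of phenotype metabolites at 20 subjects with a
false-selection rate indistinguishable from zero; at ratio 3.0
sensitivity drops to ~77%, so the selection rule's power is a steep
function of the spread — worth remembering when interpreting a real
data set's selected count.

## Numerical choices and degenerate inputs

* Strictly positive abundances are enforced at container construction,
  so log10 is total; a zero pool median is an error naming the
  metabolite, as is a zero-variance metabolite at autoscaling.
* Autoscaling and the stability SD use the n−1 denominator throughout;
  the originating software's choice is unknowable, but both choices
  give identical rankings downstream.
* Eigendecompositions use `eigen(symmetric = TRUE)`; determinism is
  imposed by the sign convention, not by the solver.
* Constant vectors make tau undefined; such slot pairs are excluded
  per metabolite with `n_pairs` decremented and flagged, never
  silently imputed.
* All randomness flows from a single integer seed per cohort spec;
  identical config + seed yields byte-identical output CSVs (the
  pipeline manifest records md5 hashes to make this checkable).

## Problem sizes used in validation

The shipped tests validate on cohorts from 1 × 8 up to the full
20 × 11 × 214 design, with simulation studies of 200 replicate null
cohorts (pre-check calibration), 100 within-subject label permutations
(Q² null), and 1000-metabolite cohorts (p-value uniformity and
stability operating characteristics). These sizes give Monte-Carlo
error well below the tested margins while keeping a full run in the
minutes range.

## Known limitations

* One model per comparison means no shared variance estimation across
  comparisons; metabolites with few subjects would suffer, though the
  default design is complete.
* The Q² convention is declared, not guaranteed to match any
  proprietary implementation bit-for-bit.
* STATIS here is the classic one-compromise variant: no dual-STATIS,
  no DISTATIS, no bootstrap confidence regions.
* The phenotype statistic treats within-day and across-day slot pairs
  identically; a day-structured variant could weight them differently.
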