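---
title: "Methods and design notes for rdnaclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for rdnaclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Crustaceans cannot be aged from hard structures: they moult their
exoskeleton and grow indeterminately, so size is a poor proxy for age.
`rdnaclock` implements an epigenetic ageing approach for the European
lobster (*Homarus gammarus*) built on percent CpG methylation of the
ribosomal DNA repeat (18S/ITS1/ITS2/28S), measured by targeted bisulphite
amplicon sequencing. The pipeline starts at per-CpG read counts (methylated
C reads vs converted T reads) and ends at an age prediction per animal plus
a von Bertalanffy growth curve linking age to carapace length.

## Methylation calling and quality control

Percent methylation at a CpG is `100 * C / (C + T)`; a cell with zero
informative reads is a *missing datum*, never 0%. A locus is dropped when
it is missing in at least one individual, or when any individual covers it
with fewer than `min_reads` (default 10) reads. Missingness is checked
first, so every dropped locus has exactly one recorded reason. Coverage is
defined as `C + T` at the CpG, not amplicon depth, and "missing in any
individual means drop" is read strictly: the downstream matrix has no
missing cells by construction. Coordinates are 1-based inclusive,
single-base intervals in the six-column Bismark-style coverage dialect.

## Per-locus screening

Each locus is regressed on age by ordinary least squares; the slope's
two-sided p-value comes from the t distribution with n − 2 df, and p-values
are corrected across loci by the Holm step-down procedure (implemented
directly: sort, multiply by m − i + 1, running maximum, cap at 1).
A locus's *saturation age* extrapolates the fitted line to the nearest
boundary: `(100 − a)/b` for hypermethylating loci, `−a/b` for
hypomethylating, infinite for flat loci. The clock origin is hatching
(age 0), the same origin the intercepts are estimated on. The screening
summary reports saturation statistics with and without the single largest
value, because a lone extreme locus can dominate the mean; this generalises
the ad hoc exclusion of one outlying locus that motivated the summary.

## The penalized-regression clock

Three penalty families are compared over one grid: ridge (α = 0), elastic
net (α = 0.5) and lasso (α = 1), with 100 λ values log-uniformly spaced on
[10⁻³, 10³]. "Ten cross-validations" is interpreted as 10-*fold* CV (the
conventional reading of the tooling involved), with folds assigned by a
seeded permutation. Predictors are standardized to zero mean / unit
variance *inside each training set*; the model stores coefficients on the
standardized scale together with the per-locus centring and scaling
parameters, so a serialized model is self-contained. λ is selected by the
median across folds of the mean absolute error; RMSE and a pooled-prediction
R² are logged per λ as well (the mean-vs-median aggregation for those is
ambiguous in common practice, so both are retained). Model comparison
prefers the lowest median MAE and breaks ties within 1% relative MAE by
fewer selected loci, encoding the usual preference for the sparser model
when accuracy is indistinguishable.

R² is reported as the squared Pearson correlation between predicted and
observed ages (the convention of the CV tooling this mirrors); 1 − SSE/SST
is also stored.

### Validation

Leave-one-out cross-validation re-runs the *entire* tuning-plus-fitting
pipeline on every training subset — selection can legitimately differ
between folds, which is the point of the protocol. Precision is the sample
SD (n − 1) of known minus predicted age; it is deliberately blind to a
constant bias. Differences are compared across cohorts by one-way ANOVA
with Tukey HSD. Two implementation details matter for reproducibility:
training samples are sorted by id before fitting, and each held-out fit
derives its fold seed from the held-out sample's id — together these make
each held-out prediction independent of sample storage order. Negative
predicted ages are reported as-is and flagged; truncation would bias the
precision statistics.

The reduced clock takes the k = 15 selected loci with highest single-locus
R² (ties broken by lower genomic position) and refits them by unpenalized
least squares. Its LOOCV holds the locus set fixed and refits the OLS
coefficients per fold: re-running selection inside each fold would measure
selection variability, not the reduced model's precision.

### Sex diagnostics

Per model locus and cohort, methylation is compared between sexes by a
two-sample t test — pooled variance unless a Brown–Forsythe (median-centred
Levene) test rejects homogeneity, then Welch — with Holm correction within
cohort and the sign of (female − male) tallied per cohort. Sex is also
tested on *predicted age* controlling for cohort via a type-II nested-model
F test. Cohorts containing a single sex are skipped with a warning.

## Growth modelling

The von Bertalanffy model `L(t) = L∞(1 − e^(−K(t − t₀)))` is fitted by
nonlinear least squares in two parameterisations: standard `(L∞, K, t₀)`
and Francis `(L₁, L₂, L₃)` — mean lengths at reference ages τ₁,
(τ₁ + τ₃)/2, τ₃, which is better conditioned when the data do not reach the
asymptote. Reference ages default to the observed age range. The two forms
are algebraically interconvertible (`r = (L₃−L₂)/(L₂−L₁) = e^(−Kh)`), and
`r → 1` is the linear-growth K → 0 limit, handled explicitly. Ages are in
months throughout; multiply-by-12 converts from years.

Fitting minimises the SSE with BFGS followed by a Nelder–Mead polish,
taking convergence from whichever optimizer terminates cleanly. This was a
deliberate choice over `nls()`: the Gauss–Newton relative-offset criterion
fails on zero-residual (noise-free) data, which the test-suite's exact
recovery checks require. Start values come from a Ford–Walford-style
log-linearisation (standard) or empirical mean lengths near the reference
ages (Francis). Confidence intervals are nonparametric case-resampling
bootstrap percentile intervals (1000 replicates by default; neither scheme
nor count is pinned by convention, and case resampling makes the fewest
assumptions); failed replicates are dropped, counted, and escalate to a
warning above 20%.

## The synthetic-data generator

The generator emulates the study design the analysis assumes so that every
stage is testable offline: seven known-age hatchery cohorts at 0, 1.8, 7.3,
12.5, 24.8, 40 and 51 months (n = 27, 29, 26, 19, 32, 5, 17; 155 total)
plus 38 unknown-age wild animals; 436 sequenced CpGs with 60% carrying a
linear methylation–age trend; negative-binomial read coverage with mean
7107 (25,253 for the 40/51-month cohorts, which form a second sequencing
batch); bisulphite conversion 99.5%, modelled as false methylation only
(`p_obs = p_true + (100 − p_true)(1 − conversion)`), since unconverted
unmethylated cytosines are the dominant error mode; and per-cell dropout.
Wild ages are drawn uniformly on [48, 108] months — only the lower bound is
externally constrained. Body sizes follow `CL = 46.2(1 − e^(−0.06(age −
3.288)))` with lognormal individual asymptotes and Gaussian measurement
error.

Defaults chosen where nothing was externally pinned, fixed once:

* `missing_rate = 0.001` per cell — with 193 samples this drops ≈18% of
  loci at QC, reproducing the 436 → ≈355 locus attrition.
* `coverage_dispersion = 5` — moderate amplicon-seq overdispersion; at mean
  7107 the sub-10-read probability is negligible, so coverage QC bites only
  through missingness, as in the study.
* `sd_individual = 2` percentage points of between-individual noise at
  every locus; informative slopes uniform on ±[0.1, 1.0] %/month with
  balanced signs (hyper- and hypomethylation both occur), baselines uniform
  on [10, 90]% so most trajectories stay unclamped over 0–51 months.
* `batch_shift = 0` and `sex_shift = 0` by default: the technical batch
  artefact and sex offsets are opt-in knobs (the sex shift can reverse sign
  per cohort), so the default world is the null against which the
  diagnostics are calibrated.
* Within-cohort age jitter defaults to 0; the recorded uncertainty (±14
  days) is small against cohort spacing.

What the generator does **not** emulate: correlated noise across loci
(assay batch chemistry, repeat-unit copy-number effects), amplicon-level
dropout (cells go missing independently), PCR amplification bias,
over-conversion of methylated cytosines, and nonlinear methylation–age
trajectories. A green test therefore establishes that the *machinery*
recovers a stated world; it does not establish field performance on real
lobsters.

## Numerical choices

* glmnet is run on pre-standardized predictors (`standardize = FALSE`) with
  the full user-supplied λ path and convergence threshold 1e-8 (tightenable
  per call); the λ = 0 OLS-limit checks use 1e-14.
* Single-locus designs are padded with an all-zero dummy column (glmnet
  requires two); its coefficient is identically zero and is dropped from
  the stored model. Training sets with fewer than 4 samples skip CV and use
  the smallest grid λ.
* Constant predictor columns standardize with scale 1 (their coefficient is
  necessarily 0); a constant-methylation locus screens as slope 0, p = 1.
* Training *RMSE* is monotone in λ (the objective penalizes squared error);
  training MAE is only near-monotone, and the tests assert exactly that.
* The workflow fans one global seed out to stages via a deterministic
  child-seed scheme (label-hashed Lehmer step), so stages can be re-run in
  isolation and whole runs are byte-identical under a fixed seed.

## Known limitations

* On the default synthetic world the full elastic-net clock is *more*
  precise relative to the reduced 15-locus clock than real data suggests:
  with independent per-locus noise, LOOCV precision scales roughly with the
  square root of the number of informative loci averaged, so the full model
  (≈110–170 selected loci) beats the 15-locus model by a factor of
  ≈1.5–1.7, while correlated real-data noise produced a smaller gap. This
  is a structural property of the independence assumption, not a tuning
  issue, and the corresponding acceptance check is intentionally left
  failing rather than widened.
* Saturation ages are linear extrapolations far beyond the calibration
  range; they are reported for model-audit purposes, not as biology.
* No nonlinear (e.g. logarithmic) age transforms are offered, and no
  alternative model families (boosting, multi-tissue clocks) — both out of
  scope by design.
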