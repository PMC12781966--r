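---
title: "Methods: bootstrap stability for backward-eliminated linear models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bootstrap stability for backward-eliminated linear models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bootsel)
```

## The model and the procedure

`bootsel` targets the setting of an observational correlate analysis: a
continuous outcome (HbA1c, in percent of total hemoglobin) and a moderate
set of candidate covariates of mixed type, some of which — age, sex, BMI,
an additive genotype dose — are retained in every model on subject-matter
grounds rather than by the data. The working model is ordinary least
squares with main effects only:

$$y_i = \beta_0 + \sum_j \beta_j x_{ij} + \varepsilon_i,
  \qquad \varepsilon_i \sim N(0, \sigma^2).$$

Binary and categorical covariates enter as treatment-coded indicators
against a declared reference level. The analysis sample is the set of
complete cases on the model variables; incomplete scale scores are handled
upstream by the imputation stage, not by the model.

**Backward elimination.** From the global model, the candidate whose
removal most lowers the Gaussian AIC is dropped, repeatedly, until no
removal lowers it. The AIC convention is the full log-likelihood form
$n\log(\mathrm{RSS}/n) + n\log 2\pi + n + 2k$ with $k$ the number of mean
parameters; the additive constants cancel in comparisons, so only the
$n\log \mathrm{RSS}$ term and the $2k$ penalty matter. For a one-parameter
removal this rule is *exactly* the likelihood-ratio partial test at
threshold $1 - F_{\chi^2_1}(2) \approx 0.157$: the term is dropped iff its
LR statistic is below 2. Categorical variables are eliminated as whole
indicator blocks, using the block's joint AIC change with the penalty
scaled by the block size; the single-step p-value equivalence then holds
at the corresponding $\chi^2_d$ threshold instead. Forced covariates and
the intercept are never candidates for removal.

**Stability investigation.** The selection procedure is repeated on $B$
bootstrap resamples (rows drawn with replacement, resample size $n$). A
variable not selected in a resample contributes a coefficient of 0. The
per-variable summaries — inclusion frequency, median-with-zeros estimate
and percentile limits, standardized estimate, RMSD ratio, relative
conditional bias — and the global summaries — selected-model frequency and
the cross-validated calibration slope — are defined in the help pages of
`bootstrap_stability()`. Two consequences of the zero-substitution
convention are worth spelling out because they are structural, not
empirical: a forced variable has inclusion frequency exactly 100 for any
data and seed, and any variable with inclusion frequency below 50% has a
median-with-zeros estimate of exactly 0 (more than half of the sorted
coefficient vector is a contiguous block of zeros that necessarily covers
the median position). The acceptance suite verifies both at full scale.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `B` | 1000 | bootstrap resamples; percentile limits need ~1000 for stable 2.5/97.5 points |
| forced set | metadata roles | covariates exempt from elimination |
| `folds` | 10 | cross-validation folds for the calibration slope; `folds = n` gives leave-one-out |
| 60% flag | fixed | reporting threshold for "meaningful" variables; not a selection step |
| imputation band | 5–10% | cohort missingness range inside which person-mean imputation is applied |
| `min_observed_fraction` | 0.5 | half-scale rule: a respondent must answer at least half the items to be imputed |
| `n_factors` | 3 | dietary patterns retained; chosen in practice from the reported eigenvalues / scree |

## Design choices where the design was open

* **"Within-domain imputation"** is implemented as respondent-level
  person-mean imputation within the instrument, after reverse-coding: a
  missing item takes the mean of the respondent's observed items on the
  same scale. The literature also uses domain-mean-across-respondents
  variants; the `impute_policy()` object records the choice rather than
  asserting there is only one reading. The band is evaluated per score
  variable on the analysis sample, and respondents still missing a score
  after imputation are dropped at modelling time (complete case).
* **Rotation criterion.** "Orthogonal rotation" is implemented as varimax
  (with Kaiser normalization), the standard choice in dietary pattern
  work; `rotation = "none"` is available.
* **Factor scores** use the regression method from the rotated solution,
  then are standardized to mean 0, SD 1 on the fitting sample, so scores
  are interpretable as adherence z-scores.
* **Categorical blocks.** Region-style categorical candidates are removed
  or retained as whole blocks. Identical inclusion frequencies for all of
  a variable's indicators are a direct signature of this treatment.
* **Shrinkage estimator.** The global shrinkage factor is the calibration
  slope of the outcome on the out-of-fold linear predictor of the selected
  model under 10-fold cross-validation. Other estimators (heuristic
  $(\chi^2-k)/\chi^2$ formulas, bootstrap slope) exist; the calibration
  slope is the one with a direct predictive interpretation.
* **Tie-breaking.** If two removals give equal AIC (within 1e-9), the term
  with the smaller largest-|t| in the current fit goes first, then
  lexicographic order. Ties have probability zero with continuous data but
  the rule makes elimination paths reproducible byte-for-byte.
* **Degenerate resamples** (a constant indicator or rank-deficient design)
  are redrawn rather than dropped, keeping $B$ — and hence every
  percentile denominator — exact. A redraw rate above 5% triggers a
  warning, since it signals a near-degenerate variable in the original
  data.
* **Stratified runs** drop the stratum variable from the forced set inside
  its own strata (it is constant there) and reuse pooled imputations
  rather than re-imputing within stratum.

## What the synthetic generator does and does not emulate

`generator_config()` encodes a cohort of n = 349 with a 53% female split,
genotype dose frequencies 0.43/0.40/0.17, anthropometry and psychosocial
scores at the means, SDs and instrument ranges typical of a Samoan adult
cohort, a BMI–abdominal-circumference correlation of 0.9 (so the VIF
diagnostic has something real to flag), and a linear outcome with effects
at published scale: age 0.020 %/year, genotype dose −0.339 %/allele,
abdominal circumference 0.035 %/cm, stress 0.032, social support 0.320,
self-efficacy −0.024, mixed-traditional diet −0.120, all other candidates
exactly 0. The residual SD of 0.54 was chosen analytically so the marginal
HbA1c SD is about 0.9 given those effects; the intercept 0.70 centres
HbA1c near 6.0%. Missingness defaults put 5–10% MCAR missingness on the
scale-score variables, the band the imputation stage is designed for.

What it deliberately does **not** reproduce: the unknown joint correlation
structure of the psychosocial scales (drawn independent here, so the
synthetic $R^2$ is higher than a real cohort's); the genotype-oversampled
survey design (representable only through the dose frequencies); household
or village clustering; and non-Gaussian outcome tails beyond a floor at
4.0%. Passing tests therefore demonstrate the *procedure's* correctness
and its structural guarantees, not that any particular real-data estimate
would be reproduced.

## Numerical conventions

Percentiles are linear-interpolation order statistics (R's default type
7), pinned for bit-reproducibility. Eigenvector sign ambiguity in the
pattern extraction is resolved by forcing each factor's largest-magnitude
loading positive, and rotated factors are ordered by explained variance.
A perfect fit (RSS = 0) makes the Gaussian AIC undefined; `model_aic()`
errors rather than returning −Inf, and the elimination loop treats a
removal that lands on RSS = 0 as non-improving. Percentages in descriptive
tables are rounded to the nearest whole percent and printed with a fixed
one-decimal style ("59.0%"), matching the reporting convention of the
field. All randomness (cohort generation, resampling, fold assignment,
missingness injection) flows from explicit integer seeds; derived seeds
stay within 32-bit range.

## Problem sizes used by the test suite

The unit suite works at n = 20–600. The acceptance suite runs the
full-scale configuration the method is specified at — one n = 349,
B = 1000 stability run shared across the forced-inclusion and median-zero
checks; 1000 random small instances against the normal-equations and
likelihood oracles; and a 20-replicate, B = 200 recovery study at n = 349
verifying that forced true effects are recovered within 25% and that
pure-noise candidates average an inclusion frequency below 40%. These
sizes are the package's own working scale for demonstrating the
properties; all are plain parameters.

## Known limitations

No generalized linear models, interactions, robust/sandwich errors,
bias-corrected bootstrap intervals, model averaging, or formal
post-selection inference corrections — the stability quantities *are* the
uncertainty report. Multiple imputation is out of scope; the person-mean
rule is a single deterministic completion. The fat-mass prediction
equation behind the fat mass index is not reimplemented; that column is
consumed as data.
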