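---
title: "Normative ENHV modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative ENHV modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhv)
```

This vignette is the package's own account of the statistics it implements:
the normative model and its assumptions, the decision procedure that selects
each region's equation, the agreement statistic used for validation, the
patient analysis battery, and — because every quantitative claim in the test
suite is made on synthetic data — a candid description of what the cohort
generator does and does not emulate.

## The normative model

For each of five regions of interest (whole brainstem, medulla, pons,
midbrain, cerebrum), the expected normal healthy volume (ENHV) of a subject
is a linear function of intracranial volume (ICV), optionally age, fitted
either on a pooled healthy cohort or separately per sex and fused with a
dummy variable (male = 1, female = 0):

* **Form 1** `ENHV = a·ICV + b` — pooled sexes, ICV only.
* **Form 2** `ENHV = (1−sex)(a_f·ICV + b_f) + sex(a_m·ICV + b_m)` — per-sex
  ICV slopes and intercepts.
* **Form 3** adds a linear age term per sex.

The underlying assumptions are those of ordinary least squares: regional
volume is linear in ICV (and age where used) with additive, homoscedastic
noise, and the sexes differ at most in slope and intercept. The model is
deliberately not a centile/GAMLSS-style normative model: it predicts a
conditional mean, not a distribution, and nonlinear or spline alternatives
are out of scope.

Units are mm³ throughout, ages in years, PTA durations in integer weeks, and
time since injury in months.

### The building procedure

`build_model()` reproduces a fixed decision path per region:

1. **Screening** (`screen_variables()`): Pearson correlation of the region's
   volume with age and with ICV, on the pooled cohort, two-sided p-values.
   A predictor is included when p < 0.05 — strictly: a p-value of exactly
   0.050 does not qualify. ICV is *always* retained as a predictor even if
   its screening p is above the threshold (the builder warns); screening can
   only add age.
2. **Interaction test** (`test_sex_icv_interaction()`): the linear model
   `volume ~ sex + ICV + sex:ICV` with ICV continuous, F-test of the
   interaction on (1, n−4) degrees of freedom. This is the "two-way ANOVA"
   of the procedure; the continuous-ICV reading is the one consistent with a
   denominator df of n−4 (a binned factorial would have different df).
   p < 0.05 → fit each sex separately.
3. **Fit** (`fit_roi_equation()`): OLS per sex subgroup when stratified,
   pooled otherwise. (stratify, use age) maps to the form: (no, no) → 1,
   (yes, no) → 2, (yes, yes) → 3. The fourth combination — pooled with age —
   has no published counterpart; we fit a pooled ICV+age regression and store
   it as a form 3 equation with identical female and male sub-equations,
   flagged `pooled_age`. Cohorts with fewer than 5 subjects of either sex
   skip the interaction test and fall back to pooled fits with a warning.

Two open choices were resolved as follows. Screening uses the *pooled*
cohort (not per-sex subsets): the screening statistics the procedure is
anchored to are pooled correlations. And age, once screened in for a region,
is kept in both sex subgroups; we do not re-test it within subgroups.

The published coefficient set (`published_model()`) is stored exactly as
printed, at three significant figures — predictions therefore carry that
rounding, which is visible in the last digits of worked examples. Model JSON
serialization writes coefficients as `%.17g` decimal text so fitted models
round-trip bit-exactly.

## Validation by ICC(A,1)

Agreement between measured volumes and model predictions on an independent
healthy cohort is quantified with the intraclass correlation for a two-way
model, single measures, absolute agreement — ICC(A,1) in the McGraw & Wong
taxonomy. With n subjects and k = 2 columns (measurement, prediction),

```
ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + (k/n)(MSC − MSE))
```

from the two-way crossed ANOVA mean squares. Absolute agreement (rather than
consistency) is essential: a model that predicts volumes perfectly correlated
with, but systematically offset from, the measurements is penalized. The 95%
confidence interval uses the standard F-based construction for ICC(A,1)
(Satterthwaite df for the lower-bound denominator), and the p-value for
ICC > 0 uses F = MSR/MSE on (n−1, (n−1)(k−1)) df, the convention of the
common ICC implementations. Negative estimates are reported as computed and
classified "poor"; estimates are not floored at zero.

Reliability bands follow the conventional cut points, read as left-closed
intervals to close the small gaps in the published table: below 0.4 poor,
[0.4, 0.6) fair, [0.6, 0.75) good, [0.75, 1] excellent. An equation is
declared valid when ICC > 0.4.

A structural point worth knowing when interpreting validation output: for a
pooled ICV-only equation, the population ICC(A,1) against the model is
`R² / (R² + (1−R²)/2)` where R² is the model's explained variance. A region
whose volume correlates with ICV at r ≈ 0.50 — the medulla is the canonical
example — therefore has a *population* ICC of ≈ 0.40: exactly at the
validity threshold. At validation sample sizes around n = 47 the medulla's
observed ICC lands above 0.4 only about half the time, while the other four
regions validate essentially always. The package reports what it computes;
users should read a medulla ICC near 0.4 as "at the edge of validity by
construction", not as a fitting failure.

## ENHV-adjusted volumes and the patient battery

`adjust_volumes()` expresses each measured volume as a percent of its ENHV
(Eq.: `100·measured/ENHV`); percent loss is its exact complement, and the
conventional proportions correction (`measured/ICV`) is carried as a
comparator. The analysis battery is nonparametric throughout, two-tailed
everywhere:

* **Between groups** (`compare_groups()`): Mann–Whitney U per variable, by
  default the family ICV + five regions (Bonferroni family size 6 — the
  family is configurable since reasonable analysts could exclude ICV).
  Exact p-values are used when both groups have ≤ 25 observations and there
  are no ties; otherwise the normal approximation with tie correction. The
  threshold of 25 keeps exact computation instant while covering the sample
  sizes this package targets.
* **Within patients** (`within_subject_region_comparison()`): Wilcoxon
  signed-rank for whole brainstem vs cerebrum; Friedman across the three
  subfields; three pairwise signed-rank tests with Bonferroni m = 3.
  All-zero paired differences are reported as p = 1 (no evidence of any
  effect) rather than as an error.
* **Severity correlations** (`pta_correlation()`): Pearson r of PTA weeks
  against adjusted volume per region, or a first-order partial correlation
  controlling time since injury, computed by the closed-form formula
  `(r_xy − r_xz·r_yz)/√((1−r_xz²)(1−r_yz²))` with a t-test on n−3 df
  (identical, to numerical precision, to correlating OLS residuals).
  P-values are reported uncorrected, as is conventional for this
  hypothesis-generating analysis.

## The synthetic cohort generator

`generator_config()` fixes the study conditions; the generators are seeded
and byte-reproducible. The healthy generator draws sex (male fraction
99/182), age uniform on 18–68 years, ICV normal with pooled mean 1.544×10⁶
mm³ and pooled SD 1.92×10⁵ mm³, and a male−female mean ICV offset of 10% of
the pooled mean — sex-specific ICV spreads are not published, and an offset
of this size is what makes the sex×ICV interaction detectable at realistic
sample sizes; the within-sex SD is derived from the pooled SD and the offset
so the pooled moments are preserved. Each regional volume is its
published-equation value plus independent Gaussian noise.

The residual SDs are not published either; they are *solved analytically*
from the published pooled ICV–volume correlations (0.614, 0.496, 0.567,
0.677, 0.828 for whole brainstem, medulla, pons, midbrain, cerebrum) using
the exact mixture-of-sexes moments of (ICV, volume). The cerebrum's age
slope comes with the published equation, so the target age correlation
(≈ −0.33) emerges without separate tuning. ICV draws are truncated at ±3.5
pooled SDs and volumes capped below 0.98·ICV: without the truncation, a
~0.1% tail of low-ICV subjects would violate the anatomical invariant
volume < ICV (the published cerebrum equation has a large intercept, so its
predictions approach the ICV itself at extreme low ICV).

The patient generator draws PTA from a discretized log-normal with median
7.5 weeks truncated to 1–26 (only the median and range are published;
log-scale SD 0.8 spreads draws across that range), time since injury
log-uniform on 5–355 months, and per-region adjusted-volume targets
`mean + r·sd·z(PTA) + noise`, where z(PTA) is the sample-standardized PTA,
the means/SDs are the published patient group summaries (86.1 ± 11.4,
91.1 ± 10.2, 83.7 ± 11.6, 88.1 ± 14.8, 92.6 ± 7.2 percent), and r targets
the published severity correlations (−0.528, −0.283, −0.537, −0.572,
−0.313). This linear latent-severity construction is the simplest mechanism
that reproduces those correlations. Measured volumes are then
`adjusted/100 × ENHV`.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: segmentation error structure (FreeSurfer noise is
neither Gaussian nor independent across regions; here residuals are
independent by construction, except through shared ICV and age),
non-linearity of volume–ICV relationships, non-uniform age distributions,
correlated atrophy across regions beyond the shared severity factor, and any
clinical heterogeneity (lesion stage, injury mechanism). Calibration
targets are means and correlations only, so tests assert bracket tolerances,
never point equality.

Cohort-engineering utilities mirror common study designs: an age-controlled
permuted-block 4:1 split (subjects sorted by age, blocks of five permuted
internally; a final short block of r subjects samples r of the five block
roles without replacement, so e.g. n = 229 yields sizes 183/46 or 184/45)
and random-number matched-control selection (top-ranked uniform draws per
sex).

## Numerical choices and edge cases

* Significance thresholds are strict `p < 0.05` everywhere; boundary cases
  (p = 0.050) are not significant.
* `icc_absolute_single()` requires n ≥ 3 (the mathematical minimum; ≥ 5
  recommended) and errors on constant input, where the ICC is undefined.
* Volumes must be strictly positive and strictly below the ICV; cohort
  validation reports the first offending row. Sex tokens M/F/male/female/0/1
  normalize to 1/0; anything else is an error, never silently defaulted.
* The cohort CSV dialect is UTF-8, comma-separated, `.` decimal, one
  canonical name per column (with a few documented aliases); doubles are
  written at shortest round-trip precision, so read∘write is the identity.
* FreeSurfer `# Measure` lines are matched case-sensitively on the canonical
  measure keys, in both the comma-separated and whitespace-separated
  dialects; the cerebrum is composed from the three summary measures, not by
  summing segmentation rows.

## Problem sizes used by the test suite

The simulation-based tests and the acceptance script run the full pipeline
at the study's natural sizes — fitting cohorts of n = 182, validation
cohorts of n = 47, control subsamples of n = 60, patient groups of n = 22 —
with 15–50 replicates per property, 200 replicates for the coefficient-bias
check, and 100 replicates in the acceptance script; the complete suite runs
in well under a minute.
Replicate counts at this scale resolve the probabilities being asserted
(majorities, high-frequency events) without chasing Monte-Carlo noise.

## Known limitations

* The published coefficients apply to Japanese and other East Asian adults;
  fitting on a local healthy cohort is the supported route elsewhere.
* A pooled ICV-only region with moderate ICV correlation has population
  ICC(A,1) near 0.4 (see above); the validity flag for such regions is
  intrinsically borderline and single-cohort validation outcomes for them
  should be read with their confidence intervals.
* Group-mean ENHV-adjusted volumes in healthy control subsamples of n = 60
  have standard errors of roughly 0.6–1.4 percentage points (given
  per-subject SDs of 4–11%), so individual cohort means routinely fall a
  point or more away from 100 even under a perfectly calibrated model.
* PTA enters as integer weeks; day-level resolution is deliberately not
  reconstructed.
* The package consumes FreeSurfer's text outputs only; it does not run or
  wrap the segmentation pipelines, and image-level I/O is out of scope.
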