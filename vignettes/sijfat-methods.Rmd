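---
title: "Quantifying sacroiliac-joint fat metaplasia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sacroiliac-joint fat metaplasia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sijfat)
```

## The scientific setting

Chemical shift-encoded MRI produces voxel-wise proton density fat fraction
(PDFF) maps. In axial spondyloarthritis (axSpA), post-inflammatory fat
metaplasia of the subchondral bone marrow of the sacroiliac joints (SIJ)
raises PDFF, and quantifying it offers an objective complement to the
conventional binary bone-marrow-edema (BME) read that anchors the current
definition of a positive SIJ MRI.

The measurement design `sijfat` models is a sampling strategy: on each of 3
consecutive semi-coronal slices, 3 circular ROIs are placed in the
subchondral bone of each of 4 quadrants (left/right sacral and iliac sides),
giving 36 ROI-level mean PDFF values per reader, with two independent
readers per subject. Subjects fall into four diagnosis groups — healthy
controls (HC), non-SpA back pain (nonSpA), non-radiographic (nr-axSpA) and
radiographic (r-axSpA) axSpA — with the two axSpA groups forming the
positive class.

Two subject-level statistics summarize a reader's grid:

* the **overall mean PDFF**, the unweighted mean of the 36 values (ROI
  areas vary between 10 and 40 mm² in the protocol, but are not recorded;
  the source tables report a single unweighted mean, so no area weighting
  is applied);
* the **exceedance count**, the number of ROIs with PDFF strictly greater
  than a threshold τ (default 70%).

Five candidate definitions of a positive SIJ MRI are built from these:
mean > 65%, count ≥ 8, each of those OR-combined with the BME read, and
BME alone. "Over" thresholds are read as strict inequalities and the count
cut-off as inclusive, following the definitions' wording; the boundary
behaviour is pinned by tests either way.

## Diagnostic-accuracy machinery

Accuracy is summarized by sensitivity, specificity, PPV and NPV from the
2×2 table against the axSpA case/non-case split, with the Youden index
J = sensitivity + specificity − 1 used to select cut-offs. Cut-off sweeps
evaluate the count rule at k = 1…36 and the mean rule at the empirical ROC
thresholds — midpoints between consecutive distinct observed subject means
(pooled over both readers), the conventional choice; the resulting ROC is
identical at every operating point to one evaluated at the observed values
themselves. Per-cut-off operating points are also **reader-averaged**
(arithmetic mean of the two readers' sensitivities and of their
specificities, Youden recomputed from the averages); predictive values are
prevalence-weighted and are not averaged. Youden ties are broken toward
higher specificity and then the higher cut-off, i.e. the more conservative
rule.

AUC is the Mann–Whitney probability with half credit for ties, and its
confidence interval uses DeLong's placement-value variance estimator —
the standard nonparametric choice when no CI method is specified.
Metrics with empty denominators are reported as `NA`, never coerced to
zero. A sensitivity analysis repeats the definition table after excluding
axSpA cases with a bDMARDs medication history ([exclude_bdmards()]),
since biologics may suppress both edema and, plausibly, fat accrual.

Inter-reader agreement uses ICC(2,1) — two-way random effects, absolute
agreement, single measures — computed from the two-way ANOVA mean squares
with F-based confidence bounds. The form is a design choice (none is named
in the source report); it is recorded in the output's `model` column so
alternates can be compared. Agreement "for the ≥8-ROI rule" is computed on
the integer exceedance counts, the continuous-like quantity consistent
with an ICC, rather than on dichotomized calls. The mean-squares estimator
can stray slightly outside [−1, 1] on adversarial data; estimates and
bounds are truncated to that range. Group comparisons use a one-way ANOVA
of subject-level mean PDFF per grouping factor — a deliberate
simplification of a repeated-measures design whose full structure (which
factors were within-subject, the adjustment method) is not reconstructable
from the published summaries — and all-pairs contrasts use Tukey's HSD, the
standard all-pairs post-hoc adjustment.

Association models are ordinary maximum-likelihood logistic regressions
(IRLS, tolerance 1e-8, ≤100 iterations) with Wald 95% intervals
exp(β ± 1.96·SE), which is the interval form implied by symmetric-on-log
published CIs. The binary outcome "extensive fat deposition" is exceedance
count ≥ 8 on reader 1's counts (configurable to reader 2 or the two-reader
mean). The multivariate model includes predictors passing a univariate
screen at p < 0.05 — the rule inferred from which predictors carry dashes
in the published multivariate columns — and is overridable. Modified-New-
York-status models are fitted among cases only, with the exceedance count
entered linearly (a per-ROI odds ratio). Apparent separation is flagged
(`converged = FALSE`) rather than silently reported.

## The cohort simulator

No raw data are deposited, so the package ships a generator
([generate_cohort()]) that emulates the study's statistical structure and
makes the whole pipeline testable. Its defaults *are* the study
conditions wherever those are printed:

| layer | default | source |
|---|---|---|
| group sizes | 34 / 24 / 37 / 52 | study composition |
| subject mean PDFF μ ± σ | 56.0±10.5, 57.6±11.6, 64.5±13.3, 72.7±15.6 | group summary table |
| BME prevalence (reader 1) | 2/34, 3/24, 18/37, 41/52 | definition table, BME row |
| covariates | age/sex/BMI normal-Bernoulli; duration & ASDAS log-normal matched to medians and IQRs | descriptive table |
| coupling slopes | log(1.15)/year duration, log(0.15) bDMARDs | multivariate ORs |

Within-subject structure is *not* identifiable from the published
summaries, so it is exposed as free parameters with defaults chosen once
to reproduce the qualitative picture — focal fat "hot spots" in controls,
diffuse deposition in long-standing disease: ROI noise SD `sigma_roi = 5`,
reader-2 remeasurement SD `sigma_reader = 3`, BME-read disagreement
`p_bme_flip = 0.05`, per-(slice, quadrant) hot-spot probability 0.10 /
0.10 / 0.20 / 0.30 rising with group severity, hot-spot elevation 20
points, and a fat-suppression factor `rho_bme_fat = 0.25` multiplying the
hot-spot probability of BME-positive subjects (edema and visible fat are
spatially mutually exclusive). Simulated disease duration is capped at 35
years: the study population is under 50 with typical onset in early
adulthood, so open log-normal tails would be unrealistic.

The hierarchy is: latent subject mean → hot-spot layer on the 12
(slice, quadrant) units → ROI noise → clip to [0, 100] → reader-2
remeasurement noise. Two calibrations make the printed summaries
recoverable *by construction*:

* the latent SD is back-solved so the realized SD of subject means equals
  the calibrated σ after adding hot-spot and ROI-noise variance;
* the latent location is solved (1-d root-find on the closed-form mean of
  a clipped normal) so the realized group mean equals μ despite hot-spot
  elevation and clipping.

Clipping still *compresses* the SD slightly for the high-PDFF group
(about 5% at the r-axSpA calibration); this is accepted rather than
back-solved, because resampling-style fixes would break the simple
monotone reproducibility of the generator.

### Coupling covariates to the outcome

For axSpA cases the extensive-fat indicator is drawn *first*, from an
exact logistic model in disease duration and bDMARDs use with a single
intercept shared by both case groups, and the fat field is then redrawn
(rejection on the whole latent layer, so accepted fields follow the exact
conditional distribution) until consistent; after 50 rounds the minimal
number of cells nearest the threshold is nudged across it. The intercept
is solved within each generated cohort so the model's mean predicted
probability equals the fat model's own marginal extensive-fat rate —
solved exactly by root-finding, since a moment-matching intercept
undershoots by Jensen's inequality.

This design makes the association-stage regression *correctly specified*:
the package's own replication experiment (100 cohorts of 2000 cases)
recovers the generative odds ratios with nominal Wald coverage. The price
is a known, documented distortion: a single-intercept propensity model
cannot reproduce the full between-group extensive-fat rate gap implied by
the group PDFF means, so in pooled cohorts a few percent of extensive-fat
mass is redistributed between nr- and r-axSpA, moving those two group
means by up to about 1.6% relative (HC and nonSpA are untouched;
single-case-group cohorts are exactly rate-matched and unbiased).
Per-group intercepts would pin every group mean but bias the pooled
regression badly (coverage collapses to ~50% in our measurements); the
package prioritizes the regression contract and documents the mean
distortion here and in the tests.

### What passing tests do and do not show

The generator emulates group-level distributions, a two-reader error
structure, and covariate–outcome effect sizes. It does **not** emulate
spatial correlation between neighbouring ROIs beyond the shared
(slice, quadrant) hot-spot, reader-specific bias (reader 2 is unbiased
noise around reader 1), ROI placement variability, erosions/ankylosis, or
longitudinal change. Pipeline results on simulated cohorts therefore
validate the *statistical machinery*, not the imaging biology; the
count-engineered fixtures ([make_fixture()]) complement them by checking
the arithmetic of every published operating point exactly.

## Numerical conventions and problem sizes

Percentages are rendered at 2 decimals with half-up rounding to match the
source tables; internal arithmetic is full precision, and report files
carry both. Degenerate inputs (constant outcomes, constant predictors,
empty subcategories, zero-variance agreement data, cohorts without cases)
are hard errors, flagged exclusions, or `NA` markers — never silent
zeros. The test suite exercises calibration at n = 2000 per group and
parameter recovery on 100 replicates of 2000 cases, sizes at which
group-mean sampling error (~0.3 points) is well below the calibration
tolerances being checked while the suite still runs in a few minutes.

## Known limitations

* The published Tables are the only calibration source; quantities they
  do not constrain (within-subject variance, reader bias, hot-spot
  geometry) are conventions, not estimates.
* The bDMARDs-excluded BME row's published NPV (52.48%) is inconsistent
  with its own per-group counts, which imply 53/78 = 67.95%; the package
  always recomputes metrics from counts and reproduces the latter.
* Whether the published AUC and the group-comparison tables used
  reader-averaged or single-reader values is unstated; both are exposed
  (`reader` arguments) and reader 1 is the default.
* The exact repeated-measures ANOVA of the source analysis is simplified
  to one-way ANOVA on subject means (see above).
* The default reader model (unbiased ROI-level noise, SD 3) yields
  near-perfect simulated agreement on subject means (ICC ≈ 0.99), because
  independent noise averages out over 36 ROIs. The more moderate
  agreement observed in practice (ICC ≈ 0.80 for mean PDFF) reflects
  correlated between-reader differences — independent ROI placement above
  all — which the cell-wise noise model does not emulate; raise
  `sigma_reader` or add a reader offset externally if that regime matters
  for a simulation study.
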