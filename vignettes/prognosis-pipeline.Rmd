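---
title: "Methods: OCT-based prognosis classification for BRVO macular edema"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OCT-based prognosis classification for BRVO macular edema}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`octprog` classifies eyes with macular edema secondary to branch retinal
vein occlusion into a good-prognosis group (A) and a poor-prognosis group
(B) over the first year of as-needed anti-VEGF maintenance, using only
information available at the first resolution of the edema. This vignette
is the package's own account of the science: the model, its assumptions,
the conventions chosen where the procedure was underdetermined, what the
synthetic cohort generator does and does not emulate, and the known
limitations.

## The outcome definition

An eye is Group A when its monthly logMAR best-corrected visual acuity
series, from the resolution visit (month 1 or 2) through month 12,
satisfies both of: the *best* value (the minimum on the logMAR scale)
reaches 0 or better, and the *worst* value never exceeds 0.15 logMAR —
the acuity standard for renewing a Japanese driver's license. Everything
else is Group B. The wording of the underlying criterion mixes "maximal"
and "minimal" acuity in a way that is contradictory if read literally on
the logMAR scale (lower logMAR = better vision); the reading implemented
in `assignGroup()` — best acuity reaches normal *and* acuity never drops
below the driving standard — is the only internally consistent one, and
is frozen as the package's definition.

## The seven handcrafted OCT features

The unit of image analysis is a trimmed B-scan: 50 lateral columns by 256
axial rows (about 0.59 mm x 0.98 mm) centered on the fovea, 8-bit
grayscale, with per-column row annotations of the ELM, EZ and RPE bands
(`NA` where the band has vanished). Conventions the package fixes:

* **Brightness standardization.** Every pixel is multiplied by
  `255 / (255 - B)`, where `B` is the mean brightness of the liquefied
  vitreous, and capped at 255 (`standardizeBrightness()`). The source
  formula defines the annotated-pixel brightness `A` but never uses it;
  a multiplicative gain applied to all pixels is the only reading that
  involves both quantities and preserves the 8-bit range. `B = 0` is the
  identity.
* **Continuity-org** (`continuityOrg()`): the sum over the 50 columns of
  the standardized brightness at the annotated row; an absent column
  contributes 1, so a fully vanished band scores exactly 50.
* **Clarity** (`layerClarity()`): per annotated column, the ratio of the
  brightness at the annotated row to the mean of the 6 pixels at rows
  r−3..r−1 and r+1..r+3 (window clamped at the grid edges, neighborhood
  mean floored at 1); absent columns contribute ratio 1. The reported
  value is the **mean** over columns, not the sum: published group means
  near 1.14 are impossible for a 50-column sum and pin the scale down.
  Continuity-org (group means in the thousands) stays a sum.
* **Area** (`areaOuterSegments()`): pixels strictly between the EZ and
  RPE rows (`rpe − ez − 1`, floored at 0) summed over columns where both
  are present. Adjacent bands enclose nothing; this strict-between rule
  is an explicit convention where the source states none.
* **Continuity grades** (`gradeContinuity()`): the clinical three-level
  judgment (vanishing / discontinuous / continuous → 0 / 1 / 2) is
  replaced by an objective surrogate on the present-column fraction f:
  grade 0 iff f = 0, grade 2 iff f = 1, grade 1 otherwise. The original
  judgment was subjective; any surrogate is a stand-in, and this one is
  the simplest that is exactly reproducible.

Rows are 1-based internally (row 1 = vitreous side); the annotation CSV
interchange format is 0-based, converted by the readers/writers.

## Variable screening

Continuous variables are compared between groups with the two-sample
Kolmogorov–Smirnov test (asymptotic p, via `stats::ks.test(exact =
FALSE)`; at group sizes 23/43 the asymptotic formula is adequate and
slightly conservative). Categorical variables use an exact Fisher r x c
(Freeman–Halton) test, implemented by full enumeration of tables with the
observed margins; the two-sided p is the total probability of tables no
more probable than the observed one, with the classical relative tie
tolerance of 1e-7 (the same convention as `stats::fisher.test`, which the
test suite uses as an independent oracle). The paired baseline-versus-
12-month acuity comparison uses a Wilcoxon signed-rank test: zero
differences dropped, exact enumeration of all 2^n sign assignments for
n ≤ 25 (mid-ranks make this valid under ties), tie-corrected normal
approximation without continuity correction above that.

Candidates are kept at p < 0.05 (strict, no multiple-testing correction —
a deliberate property of the filter design, not an oversight), then
pruned by the multicollinearity loop (`vifEliminate()`): repeatedly
remove the variable with the highest R² against the others while that
maximum exceeds 0.9 (equivalently VIF > 10), ties broken toward the
earlier column. R² is computed by least squares with an intercept; a
rank-deficient design falls back to the SVD minimum-norm solution and a
constant column counts as fully redundant (R² = 1).

## The classifier

The loss is the class-weighted L2-penalized negative log-likelihood

$$E(\alpha) = -\frac{1}{m}\sum_{i=1}^m\left[w_0\,y_i\log\sigma_i +
w_1\,(1-y_i)\log(1-\sigma_i)\right] + \frac{1}{C}\sum_{j=1}^n \alpha_j^2,
\qquad \sigma_i = \sigma(\alpha^\top x_i + b).$$

Conventions:

* Labels are y = 1 for Group B (poor prognosis), so positive
  coefficients push toward poor prognosis. The imbalance weight —
  the Group-A terms counted `nB/nA` times more — therefore attaches to
  the (1−y) terms (`w1` in `logitLoss()`). The source's symbol pairing
  presumes the opposite label coding; the coding here is the one under
  which its published coefficient signs make sense.
* The penalty is exactly `(1/C) Σ αⱼ²` — no 1/2 factor. Mappings to
  other conventions follow by rescaling; for a ridge-logistic reference
  with mean-log-likelihood objective the equivalent penalty strength is
  `lambda = 2m / (C · Σ wᵢ)`, which the test suite uses to cross-check
  the fit against `glmnet` to 1e-4.
* The intercept is included and unpenalized: the printed loss has no bias
  term, but an unpenalized intercept matches the behavior of the software
  stack the analysis describes and keeps the model translation-invariant.
* Features are z-scored with statistics computed on the training portion
  only, applied unchanged to held-out data (`standardizeFitApply()`);
  the 0/1/2 grades enter as numeric columns. Coefficients are reported on
  this standardized scale.
* The fit (`fitWeightedLogit()`) minimizes the loss by L-BFGS-B from a
  zero start — the problem is convex, so no restarts — with a projected-
  gradient tolerance of 1e-8, a relative-loss tolerance of 1e-10, and an
  iteration cap of 1000; non-convergence is flagged and warned about.

## The two-stage experiment

* **Stratified splitting** holds out `round(0.2 · class size)` per class
  with half-up rounding (23 → 5, 43 → 9), sampled uniformly within class.
* **Stage 1** repeats 100 times: split, then grid-search
  C ∈ {0.001, 0.01, 0.1, 1, 10, 100} by stratified 4-fold cross-validated
  AUC on the training 80% (one fold partition shared across the grid;
  standardization and fitting refit inside every fold). Ties break toward
  the smaller C (stronger regularization, deterministic). The modal C
  over the 100 repeats is fixed for stage 2.
* **Stage 2** repeats 100 times: split, standardize on the training part,
  fit at the fixed C with the imbalance weight, record the held-out AUC
  (rank-based Mann–Whitney with ties credited 1/2, identical to the
  trapezoidal ROC area) and the coefficients. Summaries: AUC mean ± SD;
  per-coefficient mean, SD and the 95% CI of the mean as
  mean ± 1.96·SD/√100 — the normal-approximation interval whose width
  matches the published coefficient table.
* Stage-1 and stage-2 randomness come from separate substreams of one
  master seed; the full chain is reproducible bit for bit, and the
  file-based `runPipeline()` additionally produces byte-identical
  artifacts on reruns.

## The synthetic cohort generator

`generateCohort()` emulates a 66-eye cohort (23 A / 43 B by default) so
that every pipeline stage is testable without patient data.

**Clinical covariates** are independent group-conditional draws.
Variables the original analysis found group-different (age, baseline and
resolution BCVA) use the published per-group means and SDs, truncated to
plausible ranges (age 30–95 y; logMAR ≥ −0.3). Variables without a real
group difference (sex, occlusion type, affected eye, semifield, onset
delay, time to resolution) are drawn from pooled distributions so they
stay null at any sample size; using the published per-group sex or eye
proportions verbatim would manufacture large-sample significance for
variables the analysis itself reports as non-significant (their published
percentages scatter widely at n = 23). The onset delay uses a lognormal
matched to the published mean/SD (6.86 ± 7.05 weeks): with SD above the
mean, a nonnegative truncated normal would inflate the mean by ~1.6
weeks, while the lognormal is the standard model for right-skewed delays
and preserves the target exactly. Group A's BCVA at resolution is capped
at 0.15 logMAR (its series starts there and must never exceed 0.15) and
Group B's floored at −0.1 (a poor course must stay reachable by bounded
monthly steps); both shifts to the targeted means are below 0.03 logMAR.

**BCVA series** evolve as a Gaussian random walk (monthly step SD 0.04
for A, 0.08 for B; drifts −0.010/−0.015) reflected into [−0.3, 1.5],
rejection-sampled until `assignGroup()` returns the intended group, with
a hard retry cap (500) that errors rather than loops. Label consistency
is therefore exact by construction.

**B-scans** are rendered as three Gaussian-profile bright bands (ELM, EZ,
RPE) over a noisy dark background, following a smooth row profile with a
mild parabolic curvature; the exact rendering traces become the
annotation. Group differences enter through band peak brightness, depth
blur, EZ–RPE spacing, and disruption: a grade is drawn per layer from the
published grade proportions, grade-0 layers are fully absent, grade-1
layers lose a contiguous run (or two) of columns covering 5–50% of the
width. The vitreous reference `B` is measured from the rendered top rows,
so standardization is exercised end to end. Peak/blur defaults were
calibrated once, by simulation at 200–400 replicates per group, so the
*means* of the five extracted continuous features track the published
group means (e.g. EZ continuity-org 8140 in A vs 6239 in B; clarity
1.20–1.21 vs 1.10–1.11; area 689 vs 576); the calibration constants are
frozen in `cohortSpec()` and asserted (for the EZ brightness anchor)
within 2 standard errors in the test suite. One calibration consequence
worth noting: the ELM peak must be *brighter* in Group B than A so that
gap-induced losses leave the ELM continuity-org means equal across
groups, which is exactly what the published table reports (5019 vs 5021).

**What the generator does not emulate.** Three deliberate limits matter
when reading test results:

* *No inter-feature correlation.* Only the group label links variables
  (the published analysis reports marginals only, and no covariance
  structure is invented). Nine quasi-independent features, each with
  roughly a 1-SD group separation, compound to near-perfect separation:
  synthetic stage-2 AUC sits near 1.0, above the 0.93 ± 0.08 reported on
  real (correlated) data. Tests on the synthetic cohort therefore check
  *properties* — AUC well above chance, chance-level AUC under permuted
  labels, coefficient directionality — never the published AUC value.
  Two knock-on effects: cross-validated AUC often saturates across the
  whole C grid, so the stage-1 mode is decided by near-ties (frequently
  landing on 0.001 via the smaller-C tie-break, sometimes on 10 or 100,
  rather than the 0.1 found on real data); and when a weakly regularized
  C wins, the partial coefficients of weakly informative collinear
  variables (age, the ELM grade) can flip sign even though their marginal
  direction is correct — the sign pattern holds in roughly 9 of 10 master
  seeds, not the ≥95% one would see with a strong ridge.
* *Feature SDs are not calibrated.* The absence rule prices a vanished
  band at 50 (continuity-org) or 0 (area), so the Group-B mixture over
  grades has a larger spread than the published SDs (which are in fact
  arithmetically inconsistent with 6–8 vanished eyes scoring ~50 — the
  clinical "vanishing" grade evidently did not mean an empty annotation).
  One consequence: the ELM continuity-org *distribution* differs between
  groups even with matched means, so the distribution-sensitive K-S
  screen legitimately selects it at large n.
* *No treatment mechanics.* Injection counts are drawn, not modeled; the
  retreatment decision process is out of scope.

## Problem sizes in the test suite

The suite runs the full two-stage experiment (100 + 100 repeats) on the
default 66-eye cohort, a sign-pattern sweep over 10 master seeds, a
calibration run of 400 renders per group condensed to 200 in-test, a
660-eye screen for large-sample selection behavior, a 4000-eye
covariates-only cohort for distributional convergence, 300 null cohorts
for the screen's type-I rate, and a permutation null averaged over 8
label permutations of 50 repeats each — sizes chosen so each check is
statistically meaningful at desk scale.

## Known limitations

* The subjective-grading surrogate and the standardization reading are
  explicit conventions for underdetermined steps; alternatives would
  shift feature scales (not the pipeline architecture).
* The screen tests each variable marginally and uncorrected, exactly as
  designed — it inherits that design's multiplicity behavior.
* Coefficient summaries are on the standardized scale and, like any
  penalized partial coefficients, depend on C and on which collinear
  companions are present; the directionality claims above are about
  repeat-averaged means, not individual fits.
* The published affected-eye Fisher p (0.299) is not reproducible from
  its own printed counts under any standard convention (the classical
  two-sided exact test gives 0.306); the package reports the computed
  value.
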