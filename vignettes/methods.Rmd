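---
title: "Marker-based UPF exposure and penalized spline Cox models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based UPF exposure and penalized spline Cox models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mupsurv` chains two pieces of methodology: a text-based exposure
assessment that turns product ingredient lists into per-participant
percentages of total food intake (%TFI) carrying each marker of
ultra-processing (MUP), and a penalized-spline Cox analysis that estimates
potentially nonlinear exposure–mortality curves re-expressed relative to
their HR-nadir. This vignette documents the model, its assumptions, the
tunable parameters, and the design decisions taken where the methodology
left genuine choices open.

## 1. Exposure assessment

### Lexicon and matching

The shipped lexicon (`inst/extdata/mup_lexicon.yaml`) defines 9 categories
and 57 markers, each with a set of search terms. Only the glutamate term
set (E620–E625, glutamate, glutamic acids, MSG) is fixed by primary
sources; every other term set is an editable reconstruction and flagged
`verified: false` in the file. Four markers (flavour, colour, hydrogenated
oil, fibre) are flagged as coinciding with their categories.

Matching is whole-term on a normalized token stream: lower-casing, accent
folding, punctuation collapsed to spaces, and `E 620`-style spellings glued
to `e620`. Two choices matter:

* **Segment boundaries.** Commas, semicolons, colons and brackets are hard
  boundaries; a multi-word term never matches across them. "Whole milk,
  protein hydrolysate" therefore does not contain "milk protein". This
  mirrors how a human reads an ingredient list and avoids a class of false
  positives that whole-string matching silently admits.
* **Word anchoring.** Terms match only as complete tokens (contiguous token
  runs for multi-word terms), so "discoloured" does not hit "colour".
  No fuzzy or edit-distance matching is attempted.

An item is ultra-processed if at least one marker is present.

### MLI and %TFI

For each item, up to ten researched commercial products represent the item;
the Marker Likelihood Index is the fraction of those products carrying the
marker (items with fewer than ten products use all available products as
the denominator — their MLIs are simply noisier). Product portions are
resolved to grams: gram portions as printed, millilitre portions through a
per-item specific-gravity table (default density 1.0 where no entry
exists), and descriptive portions ("Mug/Cup") through a configured
per-item standard portion standing in for packaging / standard-portion
lookups. The item's portion and energy are the means over its products.

Per participant, gram intakes are first averaged across the completed
recalls, and %TFI is the **ratio of means**:
\[
\%TFI(k) \;=\; 100 \cdot
  \frac{\overline{\text{grams carrying } k}}{\overline{\text{total grams}}} .
\]
The alternative — averaging per-recall ratios — weights a 500 g recall day
equally with a 3,000 g one and is unstable when recall totals differ; the
mean-of-intakes reading is also the natural interpretation of averaging
"dietary intake" before forming proportions. Both modes are implemented
(`build_profile(mode =)`) because the first-recall-only sensitivity variant
needs the switch anyway. Cumulative specific-MUP intake is the plain sum of
the specific-marker %TFI values (category aggregates and UPF excluded); its
unit is a %TFI-sum and can exceed 100.

## 2. Cohort pipeline

Seven exclusion criteria are applied in their printed order with first-hit
attribution (each participant is counted at the first criterion that
removes them), so the exclusion report columns sum exactly to the cohort
difference. Energy plausibility uses the Oxford (Henry) equations — shipped
as an editable coefficient table in kcal/day with weight (kg) and height
(m) terms for three adult age bands per sex — and excludes intakes of
0 kcal, below \(1.1\cdot BMR - 500\), above \(2.5\cdot BMR + 500\), or in
the population's top 0.1%. Two readings of "top 0.1%" are possible; the
package interprets it as the 99.9th percentile of total energy intake in
the pre-exclusion recall-completing population, computed within criterion
7 after the BMR bounds. Bounds are strict inequalities: a value exactly at
a bound is retained.

Follow-up runs from the last dietary assessment to death, loss to
follow-up, or the administrative cutoff (2022-12-19), whichever is first.
Quintile covariates (age, MET, SBP, Townsend) are split at the analysis
cohort's own quintiles — i.e. after all exclusions — which keeps the splits
invariant under monotone rescaling of the covariate.

## 3. Penalized spline Cox model

Exposure and total energy intake enter as cubic B-spline terms with 8 base
functions over the observed exposure range (equally spaced interior knots;
with boundary multiplicity the knot vector has \(8 + 4 = 12\) entries).
Energy uses the same basis size — the methodology implies but does not fix
this, and a common basis keeps the two smooth terms comparable.

* **Identifiability.** Cubic B-spline rows sum to one, so a constant
  coefficient vector shifts the linear predictor by a constant that the
  partial likelihood cannot see. Each spline block is reparametrized
  orthogonally to the constant direction (sum-to-zero), leaving 7 free
  coefficients per term.
* **Penalty.** The roughness penalty is the exact integral of the squared
  second derivative (O'Sullivan penalty; Simpson's rule is exact because
  cubic-spline second derivatives are piecewise linear). Its null space is
  exactly the linear functions of the exposure, so as \(\lambda \to \infty\)
  the fit collapses onto the ordinary linear Cox fit — the test suite
  checks agreement with an independent `survival::coxph` fit to 1e-3
  relative slope error. Coefficient-difference penalties were rejected:
  with clamped boundary knots their effective curvature weights are ~9×
  larger near the boundary, which systematically flattened the outer limbs
  of J-shaped curves in cross-checks against the reference implementation.
* **Effective df.** \(\lambda\) per term is tuned by 1-D root finding so
  that \(\mathrm{tr}\big[(H+P)^{-1}H\big]\) restricted to the term equals a
  target (default 4, the convention of the survival ecosystem's `pspline`;
  configurable). The penalty matrix is normalized to unit diagonal scale so
  \(\lambda\) is dimensionless across exposure units.
* **Ties and optimization.** Breslow ties; Newton–Raphson with step
  halving on the penalized partial likelihood. The blockwise risk-set
  accumulation has ~1e-8 absolute arithmetic noise, so step acceptance and
  convergence use tolerances relative to the log-likelihood magnitude, and
  a step below 1e-7 relative norm is treated as converged. Factor columns
  that become single-level after exclusions are dropped from the design.
* **Covariances.** The linear-effect Wald test and slope CI use the
  sandwich covariance \((H+P)^{-1}H(H+P)^{-1}\): the linear direction is
  unpenalized, so the sandwich is the correct frequentist variance of the
  penalized estimator there, and in null-calibration pilots the
  Bayesian-type \((H+P)^{-1}\) was measurably conservative while the
  sandwich tracked the nominal level (the shipped 200-replicate
  calibration test re-establishes this on every run). The non-linear Wald
  test (on the component orthogonal to the constant and linear directions,
  with \(edf - 1\) degrees of freedom) keeps \((H+P)^{-1}\), the usual
  choice for shrunk spline components.

### PH diagnostics and stratification

Scaled-Schoenfeld score tests (Grambsch–Therneau form, Kaplan–Meier time
transform, factor columns tested jointly) are run per covariate on the
fitted penalized model; `survival::cox.zph` operates only on `coxph`
objects, hence the in-package implementation, validated by its calibration
behaviour (nominal null rate; a planted hazard-ratio jump is detected and
stratified). P-values are Holm-adjusted across covariates; violators move
into the baseline-hazard strata and the model is refit **once** — no
re-diagnosis loop, matching a single-pass adjustment step.

### HR-nadir curves

The spline linear predictor is evaluated on 512 equally spaced points from
\(\max(0, \min x)\) to the 99th percentile of observed intake; the nadir is
the grid argmin with ties broken toward the smallest exposure
(deterministic, and curves are read at coarse %TFI resolution anyway). The
curve is rescaled so HR(nadir) = 1. Pointwise CIs use the variance of the
contrast \(\eta(x) - \eta(\text{nadir})\) under the penalized covariance,
which makes the interval width zero at the reference and accounts for the
reference point's own uncertainty; a `ref_fixed` flag provides the
fixed-reference variant for comparison. `hr_at()` interpolates linearly in
log-HR (midpoints carry geometric means) and refuses extrapolation.

## 4. Sensitivity harness

The 17 variants each change exactly one aspect of the main analysis:
cohort filters (landmark ≥2 years, weight loss, non-typical diet,
single-recall, prior CVD/cancer), first-recall exposure, covariate deltas
(diet-quality score, WHR+height for BMI, energy removal, medication flags,
BMI/SBP as splines, assessment centre), truncated-product MLIs
(k = 8, 6, 4; k = 10 reproduces the main analysis bit-identically, which
the tests assert), cumulative specific-MUP exposure, and Benjamini–Hochberg
adjustment applied separately to the category family and the
specific-marker family. Variants 10–11 (relaxed exclusions with kNN /
random-forest imputation) expose a pluggable imputer hook and record a
"delegated" status when none is registered — imputation internals are
deliberately out of scope. Diet quality, medications and centre are
synthetic stub covariates: their real-data construction is not modelled.

## 5. The synthetic-data generator

The generator defines the study conditions under which the package is
exercised:

* **Catalogue.** 238 items × 10 products. An item is marker-carrying with
  probability 0.25; a carrying item's recipe includes each marker with the
  prevalences in `default_marker_prevalence()` (flavour most common at
  0.60, trace markers at ≤0.01); each recipe marker then appears in a given
  product with probability drawn from U(0.5, 1). Ingredient texts are
  assembled from filler tokens plus randomly typeset surface terms
  (`E 621` vs `e621`, case variation). Only surface terms that scan back
  to exactly their own marker are inserted, so the inserted-marker ground
  truth is well defined; markers whose whole vocabulary nests inside
  another marker's (e.g. "smoke flavouring" vs "flavour") are never
  inserted.
* **Recalls and covariates.** 5,000 participants by default; 1–5 recalls
  with probabilities (.35, .25, .18, .12, .10); per-item consumption
  probabilities scaled so expected intake is ~10 items/day independent of
  catalogue size; covariate marginals chosen to resemble a UK cohort
  baseline table (age 58 (8) within 40–75, 57% female, BMI ≈ 27 (4.8),
  SBP 138.5 (19.4), Townsend −1.7 (2.8), MET ≈ 4,100/week, mean energy
  ≈ 9,000 kJ/day). Energy densities U(80, 520) kJ/100 g keep daily energy
  inside the Oxford-equation plausibility bounds for most participants.
* **Survival.** Weibull baseline (shape 1.3, scale 59 years — ~12% ten-year
  mortality at the reference) scaled by
  \(\exp\{\eta_{true}(\text{exposure}) + \eta_{cov}\}\) via inverse
  transform; administrative censoring at 2022-12-19 plus a small random
  loss-to-follow-up rate (0.002/year). The default true curve is J-shaped
  with nadir 18 %TFI and curvatures \(a_{left} = 1.2\times10^{-3}\),
  \(a_{right} = 1.6\times10^{-3}\) per (%TFI)². These were set by a
  scaled-down power design: desk-scale recovery runs use roughly 1,300
  events versus the ~10,000 of a full-scale cohort, so curvature is scaled
  up by \(\sqrt{10{,}000/1{,}300} \approx 2.8\) relative to a full-scale
  curve whose HR contrast at 50 %TFI is ≈1.19, keeping the
  curvature-to-noise ratio comparable.
* **Seeds.** One root seed; stages derive sub-seeds (+1 catalogue, +2
  cohort, +3 survival) so stages regenerate independently and outputs are
  byte-identical under a fixed seed.

What the generator does **not** emulate: real retailer phrasing beyond
token pools, correlated food-group consumption, exposure–covariate
confounding (covariates and diet are drawn independently), cause-specific
mortality, and real questionnaire structure (follow-up sub-questions are
folded into their parent items). Passing tests therefore demonstrate that
the pipeline recovers what it is defined to compute under known truth —
not that the lexicon's reconstructed term sets match any particular
product market.

## 6. Problem sizes and what the tests show

The test suite runs the worked examples exactly; oracle equivalence on
n = 1,000 cohorts; null calibration on 200 replicates of n = 2,000 (linear
test rejections within the binomial 95% band of 0.05; Holm-adjusted
stratification in ≤10% of PH-true replicates); nadir recovery on 50
replicates of n = 10,000 (within ±3 %TFI in ≥80%) with slope-CI coverage
on 200 replicates of n = 2,000; and exact pipeline identities (scanned MLI
= inserted-marker truth; %TFI = ground truth to 1e-12, i.e. floating-point
reassociation only; the k = 10 truncation bit-identical to the main
analysis). These sizes keep a full run within a few minutes on one core
while leaving each check statistically meaningful.

## 7. Known limitations

* The nadir is identifiable only when both limbs of the curve carry data;
  with the exposure mass concentrated on one side the estimated curve is
  effectively monotone and the nadir collapses to the boundary
  (`analysis/04_fit_curves.R` demonstrates this on purpose).
* Effective-df tuning targets a fixed df rather than optimizing a
  criterion such as AIC; this mirrors the reference ecosystem's default
  but is a convention, not an optimum.
* The Grambsch–Therneau test used here is the classical score-test
  approximation, not the exact augmented-model score test of recent
  `survival` releases; its calibration is validated by simulation.
* Holm/BH adjustments delegate to `stats::p.adjust`; imputation variants
  require a user-supplied imputer.
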