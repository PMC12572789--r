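# mupsurv

Quantifying ultra-processed-food exposure from ingredient lists and
estimating its nonlinear association with all-cause mortality.

## The problem

Most epidemiological work on ultra-processed food (UPF) classifies whole
foods into NOVA group 4 by expert judgement. An alternative is to work from
what is actually printed on products: **markers of ultra-processing (MUPs)**
— cosmetic additives and industrial ingredients (flavourings, colourings,
sweeteners, emulsifiers, modified oils, protein isolates, added fibres,
varieties of sugar) whose presence on an ingredient list flags a product as
ultra-processed. `mupsurv` implements this marker-based exposure assessment
and the survival modelling that goes with it:

* **Lexicon scanning** — a 9-category / 57-marker lexicon (editable YAML;
  term sets include E-number spellings such as `E621`/`E 621`) is matched
  against free-text ingredient lists as whole-word token sequences, with
  commas treated as hard segment boundaries. A food item is UPF if it
  contains at least one MUP.
* **Marker Likelihood Index (MLI)** — for each diet-questionnaire item, up
  to ten researched commercial products stand in for the item;
  `MLI(item, marker) = (# products whose list carries the marker) / (# products)`.
  Example: six of ten chocolate-bar products carry a flavour term, so the
  flavour MLI is 0.6, and a 50 g portion contributes 50 × 0.6 = 30 g of
  flavoured food.
* **%TFI exposures** — per participant,
  `%TFI(marker) = 100 × (mean daily grams carrying the marker) / (mean daily grams eaten)`,
  averaged over up to five 24-h recalls (ratio of means); cumulative
  specific-MUP intake is the sum of the specific-marker %TFI values.
* **Penalized spline Cox models** — exposure and total energy intake enter
  a Cox model as cubic B-splines (8 base functions, hence 12 knots) with a
  curvature penalty tuned to a target effective df (default 4), adjusted
  for the usual covariate set (age, alcohol, BMI, ethnicity, general
  health, qualification, psychiatric history, income, physical activity,
  SBP, sex, smoking, Townsend index, as quintile or fixed-band factors).
  Scaled-Schoenfeld score tests with Holm adjustment move
  proportional-hazards violators into the baseline strata (single pass);
  spline effects are split into linear and non-linear components.
* **HR-nadir curves** — the fitted hazard ratio is evaluated on
  [0, 99th percentile of intake], rescaled so the lowest point (the
  HR-nadir) equals 1, with pointwise 95% CIs.
* **Synthetic studies** — a generator emulates all inputs (product
  catalogue with ingredient texts, recalls, Table-1-like covariates,
  Weibull survival with a configurable true exposure–log-hazard curve) with
  recorded ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(mupsurv)
lex <- default_lexicon()

scan_ingredients("Sugar, FLAVOURING (E 621)", lex)
#> [1] "flavour"   "glutamate"

# 6 of 10 products flavoured -> MLI 0.6; 50 g portion -> 30 g flavoured
item_marker_grams(portion_g = 50, mli = 0.6)
#> [1] 30

# flavour 3 + acesulfame 2 + emulsifier 5 %TFI -> cumulative intake 10
cumulative_intake(c(flavour = 3, acesulfame = 2, emulsifier = 5))
#> [1] 10
```

The `analysis/` directory holds the full workflow as numbered drivers
(`01_simulate.R` … `05_sensitivity.R`): generate a synthetic study, score
exposures, apply the seven exclusion criteria, fit the spline Cox models,
and re-run everything under the 17 sensitivity variants. Running them in
order prints, among other things:

```
Generated 2380 products for 238 items; 119100 recalls; 5000 participants (775 deaths).
Max |scanned MLI - true MLI| = 0 (exact recovery expected).
Analysis cohort: n = 3923, deaths = 596, median follow-up 11.3 years.
UPF                    nadir   0.0 %TFI  p_lin 2.3e-73  p_nonlin 1.1e-26
UPF significant (linear or non-linear p < 0.05) in 18 of 18 completed columns;
Delegated (no imputer registered): v10, v11
```

The text scanner recovers the generator's inserted-marker MLIs exactly, and
the UPF–mortality association survives every completed sensitivity variant.
In this demonstration cohort only 23% of participants sit below the true
HR-nadir (18 %TFI), so the fitted curve is effectively monotone and its
nadir collapses to the boundary — the test suite's dedicated recovery
simulations (n = 10,000 with exposure mass centred near the nadir) show the
nadir is located to within ±3 %TFI in ≥80% of replicates when both limbs
are observed.

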