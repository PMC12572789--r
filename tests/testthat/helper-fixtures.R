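# Shared fixture builders (everything generated in code; no stored data).

# Product table for one item: n_with texts carry a flavour term, the rest
# only safe fillers.
flavour_products <- function(n_with, n_total, item_id = "item001",
                             portion_g = 50, energy = 2000) {
  if (n_total == 0L)
    return(data.frame(item_id = character(0), product_id = character(0),
                      ingredients_text = character(0), portion_g = numeric(0),
                      energy_kj_100g = numeric(0)))
  fillers <- c("Wheat flour", "Cocoa butter", "Salt", "Whole milk", "Oats")
  txt <- vapply(seq_len(n_total), function(j) {
    base <- paste(sample(fillers, 3), collapse = ", ")
    if (j <= n_with) paste0(base, ", Flavouring") else base
  }, character(1))
  data.frame(item_id = item_id,
             product_id = sprintf("%s_p%02d", item_id, seq_len(n_total)),
             ingredients_text = txt,
             portion_g = portion_g,
             energy_kj_100g = energy,
             stringsAsFactors = FALSE)
}

# Weibull PH survival draw used across Cox tests: baseline shape 1.3 /
# scale 59, uniform administrative censoring in 8-13 years.
sim_surv <- function(n, eta, cens_lo = 8, cens_hi = 13,
                     shape = 1.3, scale = 59) {
  tt <- stats::rweibull(n, shape, scale) / exp(eta / shape)
  cens <- stats::runif(n, cens_lo, cens_hi)
  data.frame(time = pmin(tt, cens), status = as.integer(tt <= cens))
}

# Minimal participant table satisfying the cohort-pipeline column contract.
clean_participants <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    sex = sample(c("male", "female"), n, TRUE),
    age_years = runif(n, 41, 74),
    height_m = runif(n, 1.5, 1.95),
    weight_kg = runif(n, 50, 110),
    bmi_kg_m2 = runif(n, 19, 34),
    sbp_mmHg = runif(n, 110, 170),
    smoking_status = sample(c("never", "previous", "current"), n, TRUE),
    alcohol_g_day = runif(n, 0, 40),
    ethnicity = "white",
    general_health = sample(c("poor", "fair", "good", "excellent"), n, TRUE),
    qualification = sample(letters[1:5], n, TRUE),
    psychiatric_history = FALSE,
    income_band = sample(c("<18", "18 to <31", "31 to <52"), n, TRUE),
    met_per_week = runif(n, 500, 9000),
    townsend = rnorm(n, -1.7, 2.8),
    malabsorption = FALSE,
    diabetes = FALSE,
    prior_cvd_cancer = FALSE,
    unintentional_weight_loss = FALSE,
    diet_not_typical = FALSE,
    last_assessment_date = as.Date("2010-06-01"),
    death_date = as.Date(NA),
    lost_date = as.Date(NA),
    n_recalls = 2L,
    stringsAsFactors = FALSE
  )
}

# A small complete synthetic study reused by pipeline-level tests.
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 424, n_items = 50, n_participants = 700,
                        missing_prob = 0.01)
      cache <<- gen_study(cfg)
    }
    cache
  }
})

# UPF %TFI distribution at the generator's default scale (238 items), used
# as the exposure marginal in calibration/recovery simulations.
upf_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 2424, n_participants = 4000)
      cache <<- gen_cohort(cfg, gen_catalogue(cfg))$truth$tfi[, "UPF"]
    }
    cache
  }
})
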