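## Synthetic study generator -------------------------------------------------
##
## Emulates the four inputs of the exposure/mortality pipeline with known
## ground truth: a product catalogue with ingredient texts assembled from
## marker search terms and safe filler tokens, 24-h dietary recalls, a
## Table-1-like covariate panel, and Weibull proportional-hazards survival
## times driven by a configurable true exposure-log-hazard curve.

## Filler ingredient tokens, checked (tests) to never match any lexicon term.
sim_filler_pool <- c(
  "water", "salt", "wheat flour", "whole milk", "cocoa mass", "cocoa butter",
  "rice", "oats", "tomato puree", "onion powder", "garlic", "yeast",
  "butter", "cream", "palm oil", "sunflower oil", "maize starch", "raisins",
  "almonds", "honey", "vinegar", "mixed spices", "dried herbs", "chicken",
  "beef", "peas", "carrot", "potato", "sea salt", "olive oil", "egg",
  "skimmed milk powder", "dark chocolate", "strawberries", "apple juice",
  "orange concentrate", "malted barley", "rye flour", "coconut", "basil"
)

#' Default per-marker prevalence among marker-carrying items
#'
#' Probability that a marker-carrying ("UPF-type") item's recipe includes
#' each marker; chosen so that realized exposure marginals resemble a
#' population whose mean UPF intake is around 20 \%TFI with flavour the most
#' common category.
#' @return named numeric vector over the 57 default markers.
#' @export
default_marker_prevalence <- function() {
  c("flavour" = 0.60, "smoke flavouring" = 0.02,
    "glutamate" = 0.05, "ribonucleotide" = 0.03, "yeast extract" = 0.08,
    "hydrolysed protein" = 0.03,
    "colour" = 0.30, "annatto" = 0.03, "carmine" = 0.02,
    "caramel colour" = 0.05, "carotene" = 0.06,
    "acesulfame" = 0.06, "aspartame" = 0.05, "cyclamate" = 0.01,
    "saccharin" = 0.04, "sucralose" = 0.06, "thaumatin" = 0.005,
    "neohesperidine" = 0.005, "steviol glycoside" = 0.02, "neotame" = 0.005,
    "advantame" = 0.002,
    "caking agent" = 0.05, "firming agent" = 0.04, "gelling agent" = 0.06,
    "thickener" = 0.20, "emulsifier" = 0.30, "stabiliser" = 0.20,
    "humectant" = 0.05, "glazing agent" = 0.03, "bulking agent" = 0.02,
    "foaming agent" = 0.01,
    "fructose" = 0.15, "inverted sugar" = 0.05, "lactose" = 0.12,
    "maltodextrin" = 0.18, "glucose syrup" = 0.20,
    "hydrogenated oil" = 0.02, "interesterified oil" = 0.005,
    "fractionated oil" = 0.01,
    "whey protein" = 0.06, "casein" = 0.05, "soy protein" = 0.04,
    "pea protein" = 0.02, "gluten" = 0.12, "collagen" = 0.01,
    "gelatine" = 0.05, "milk protein" = 0.05, "egg white powder" = 0.01,
    "mechanically separated meat" = 0.01,
    "fibre" = 0.08, "inulin" = 0.03, "oligofructose" = 0.01,
    "polydextrose" = 0.02, "resistant starch" = 0.01, "beta glucan" = 0.01,
    "psyllium" = 0.01, "cellulose" = 0.04)
}

#' Simulation configuration
#'
#' @param seed root seed; stage seeds are derived as seed+1 (catalogue),
#'   seed+2 (cohort), seed+3 (survival) so stages regenerate independently.
#' @param n_items number of WebQ-style items (238 = 206 foods + 32 beverages).
#' @param products_per_item products researched per item (<= 10).
#' @param p_upf_item probability an item is marker-carrying at all.
#' @param marker_prevalence named per-marker recipe probabilities (within
#'   marker-carrying items).
#' @param inclusion_range per-product inclusion probability of an item's
#'   recipe markers is drawn uniformly from this range.
#' @param n_participants cohort size.
#' @param recall_probs distribution of the number of completed recalls (1-5).
#' @param consume_range per-item daily consumption probability range at the
#'   reference catalogue size of 238 items; probabilities are rescaled by
#'   238/n_items so expected daily intake does not depend on catalogue size.
#' @param missing_prob covariate missingness probability (exclusion testing).
#' @param truth true exposure-log-hazard curve: list(type = "null", "linear"
#'   (slope beta per \%TFI) or "jshape" (nadir x0, left/right curvatures));
#'   plus Weibull baseline shape/scale and the administrative cutoff.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_items = 238L,
                       products_per_item = 10L,
                       p_upf_item = 0.25,
                       marker_prevalence = default_marker_prevalence(),
                       inclusion_range = c(0.5, 1),
                       n_participants = 5000L,
                       recall_probs = c(0.35, 0.25, 0.18, 0.12, 0.10),
                       consume_range = c(0.01, 0.075),
                       missing_prob = 0.01,
                       truth = list(type = "jshape", nadir = 18,
                                    a_left = 1.2e-3, a_right = 1.6e-3,
                                    beta = 0.01,
                                    weibull_shape = 1.3, weibull_scale = 59,
                                    loss_rate = 0.002),
                       cutoff_date = as.Date("2022-12-19")) {
  structure(as.list(environment()), class = "sim_config")
}

random_typography <- function(term) {
  style <- sample.int(3L, 1L)
  out <- switch(style, toupper(term), term,
                paste0(toupper(substr(term, 1, 1)), substr(term, 2, nchar(term))))
  # occasionally spell E-numbers with a space: "E 621"
  if (grepl("^e\\d", term) && stats::runif(1) < 0.5)
    out <- sub("^([eE])", "\\1 ", out)
  out
}

#' Generate a synthetic product catalogue with known MLI ground truth
#'
#' @param config a \code{\link{sim_config}}.
#' @param lexicon the lexicon whose terms seed the ingredient texts.
#' @return list: \code{catalogue} data.frame (item_id, product_id,
#'   ingredients_text, portion_value, portion_unit, energy_kj_100g),
#'   \code{gravity} and \code{fallback_g} named vectors, and \code{truth}
#'   with the inserted-marker MLI matrix (items x exposure keys, computed
#'   from the generator's insertion indicators, not from text scanning),
#'   true mean portions (g), energies, and per-item consumption
#'   probabilities.
#' @export
gen_catalogue <- function(config = sim_config(), lexicon = default_lexicon()) {
  set.seed(config$seed + 1L)
  n_items <- config$n_items
  npp <- config$products_per_item
  ids <- sprintf("item%03d", seq_len(n_items))
  markers <- lexicon$marker_names
  prev <- config$marker_prevalence[markers]
  prev[is.na(prev)] <- 0
  names(prev) <- markers
  ## only surface terms that scan back to exactly their own marker keep the
  ## inserted-marker ground truth well defined; markers whose every term is
  ## ambiguous (e.g. nested in another marker's vocabulary) are not inserted
  terms_of <- lapply(seq_along(markers), function(k) {
    ts <- lexicon$markers[[k]]$search_terms
    ts[vapply(ts, function(t)
      identical(scan_ingredients(t, lexicon), markers[k]), logical(1))]
  })
  names(terms_of) <- markers
  prev[lengths(terms_of) == 0L] <- 0

  rows <- vector("list", n_items * npp)
  inserted <- array(FALSE, dim = c(n_items, npp, length(markers)),
                    dimnames = list(ids, NULL, markers))
  portion_value <- matrix(0, n_items, npp)
  portion_unit <- character(n_items)
  gravity <- stats::setNames(rep(NA_real_, n_items), ids)
  fallback_g <- stats::setNames(rep(NA_real_, n_items), ids)
  energy <- matrix(0, n_items, npp)
  true_portion_g <- matrix(0, n_items, npp)

  for (i in seq_len(n_items)) {
    upf_type <- stats::runif(1) < config$p_upf_item
    recipe <- if (upf_type) markers[stats::runif(length(markers)) < prev]
    else character(0)
    incl_p <- stats::setNames(stats::runif(length(recipe),
                                           config$inclusion_range[1],
                                           config$inclusion_range[2]), recipe)
    unit <- sample(c("g", "ml", "Mug/Cup"), 1L, prob = c(0.70, 0.15, 0.15))
    base_portion <- stats::runif(1, 30, 350)
    portion_unit[i] <- unit
    if (unit == "ml") gravity[i] <- stats::runif(1, 0.9, 1.1)
    if (unit == "Mug/Cup") fallback_g[i] <- round(stats::runif(1, 150, 350))
    for (j in seq_len(npp)) {
      fillers <- sample(sim_filler_pool, sample(4:9, 1L))
      present <- recipe[stats::runif(length(recipe)) < incl_p]
      inserted[i, j, present] <- TRUE
      surface <- vapply(present, function(m)
        random_typography(sample(terms_of[[m]], 1L)), character(1))
      txt <- paste(sample(c(fillers, surface)), collapse = ", ")
      pv <- switch(unit,
                   g = base_portion * stats::runif(1, 0.8, 1.2),
                   ml = base_portion * stats::runif(1, 0.8, 1.2),
                   1)   # descriptive portion ("Mug/Cup")
      portion_value[i, j] <- pv
      true_portion_g[i, j] <- switch(unit, g = pv, ml = pv * gravity[i],
                                     fallback_g[i])
      energy[i, j] <- stats::runif(1, 80, 520)
      rows[[(i - 1L) * npp + j]] <- data.frame(
        item_id = ids[i], product_id = sprintf("%s_p%02d", ids[i], j),
        ingredients_text = txt, portion_value = pv, portion_unit = unit,
        energy_kj_100g = energy[i, j], stringsAsFactors = FALSE)
    }
  }

  keys <- exposure_keys(lexicon)
  truth_mli <- matrix(0, n_items, length(keys), dimnames = list(ids, keys))
  for (i in seq_len(n_items)) {
    hits <- inserted[i, , , drop = TRUE]
    if (is.null(dim(hits))) hits <- matrix(hits, nrow = npp)
    truth_mli[i, markers] <- colMeans(hits)
    for (cc in lexicon$categories) {
      member <- markers[lexicon$category_of == cc]
      truth_mli[i, paste0("category:", cc)] <-
        mean(rowSums(hits[, member, drop = FALSE]) > 0)
    }
    truth_mli[i, "UPF"] <- mean(rowSums(hits) > 0)
  }

  list(catalogue = do.call(rbind, rows),
       gravity = gravity[!is.na(gravity)],
       fallback_g = fallback_g[!is.na(fallback_g)],
       truth = list(
         mli = truth_mli,
         inserted = inserted,
         mean_portion_g = stats::setNames(rowMeans(true_portion_g), ids),
         mean_energy_kj_100g = stats::setNames(rowMeans(energy), ids),
         consume_prob = stats::setNames(
           pmin(0.9, stats::runif(n_items, config$consume_range[1],
                                  config$consume_range[2]) * 238 / n_items),
           ids)))
}

## Independent ground-truth %TFI: plain loops over the generator's own
## bookkeeping (true MLIs and true portion grams), mirroring the declared
## ratio-of-means definition without going through the scanning pipeline.
truth_profiles <- function(recalls, cat_truth, mode = "mean_over_recalls") {
  keys <- colnames(cat_truth$mli)
  parts <- split(recalls, recalls$participant_id)
  ids <- names(parts)
  tfi <- matrix(NA_real_, length(ids), length(keys), dimnames = list(ids, keys))
  total_g <- numeric(length(ids))
  for (i in seq_along(parts)) {
    rec <- parts[[i]]
    if (mode == "first_recall")
      rec <- rec[rec$recall_index == min(rec$recall_index), , drop = FALSE]
    rix <- unique(rec$recall_index)
    tot <- 0; mk <- numeric(length(keys))
    for (r in rix) {
      rr <- rec[rec$recall_index == r, , drop = FALSE]
      grams <- rr$n_portions * cat_truth$mean_portion_g[as.character(rr$item_id)]
      tot <- tot + sum(grams)
      mk <- mk + drop(crossprod(cat_truth$mli[as.character(rr$item_id), ,
                                              drop = FALSE], grams))
    }
    tot <- tot / length(rix); mk <- mk / length(rix)
    tfi[i, ] <- 100 * mk / tot
    total_g[i] <- tot
  }
  list(participant_id = ids, tfi = tfi, total_food_g = total_g)
}

#' Generate a synthetic cohort: recalls and covariates
#'
#' Covariate marginals loosely follow a UK-cohort baseline table (age 58 (8)
#' within 40-75, 57\% female, BMI around 27, SBP 138 (19), Townsend -1.7
#' (2.8), MET about 4100/week); recall counts follow the configured 1-5
#' distribution; per-recall item consumption uses the catalogue's per-item
#' probabilities.
#'
#' @param config a \code{\link{sim_config}}.
#' @param cat a \code{\link{gen_catalogue}} result.
#' @return list(participants, recalls, truth = independent ground-truth
#'   \%TFI profiles).
#' @export
gen_cohort <- function(config = sim_config(), cat = gen_catalogue(config)) {
  set.seed(config$seed + 2L)
  n <- config$n_participants
  pid <- sprintf("P%06d", seq_len(n))

  sex <- ifelse(stats::runif(n) < 0.573, "female", "male")
  age <- pmin(pmax(stats::rnorm(n, 58, 8), 40), 75)
  height <- ifelse(sex == "male", stats::rnorm(n, 1.76, 0.07),
                   stats::rnorm(n, 1.63, 0.06))
  bmi <- pmin(pmax(stats::rnorm(n, 27, 4.8), 16), 48)
  weight <- bmi * height^2
  sbp <- stats::rnorm(n, 138.5, 19.4)
  smoking_levels <- c("never", "previous", "current occasional",
                      "current <10 cigarettes per day",
                      "current 10 to 14 cigarettes per day",
                      "current 15 to 19 cigarettes per day",
                      "current >=20 cigarettes per day")
  smoking <- sample(smoking_levels, n, replace = TRUE,
                    prob = c(0.575, 0.353, 0.024, 0.012, 0.011, 0.010, 0.015))
  alcohol <- stats::rlnorm(n, log(8), 1.2)
  ethnicity <- ifelse(stats::runif(n) < 0.964, "white", "other")
  gen_health <- sample(c("poor", "fair", "good", "excellent"), n, TRUE,
                       prob = c(0.024, 0.160, 0.607, 0.209))
  qualification <- sample(c("none", "national exams age 16",
                            "vocational or ages 17-18", "professional",
                            "college or university"), n, TRUE,
                          prob = c(0.080, 0.151, 0.177, 0.156, 0.437))
  psych <- stats::runif(n) < 0.066
  income <- sample(c("<18", "18 to <31", "31 to <52", "52 to <100", ">=100",
                     "unknown"), n, TRUE,
                   prob = c(0.134, 0.219, 0.260, 0.223, 0.066, 0.098))
  met <- stats::rgamma(n, shape = 2.43, scale = 1701)
  townsend <- stats::rnorm(n, -1.7, 2.8)
  whr <- ifelse(sex == "male", stats::rnorm(n, 0.93, 0.06),
                stats::rnorm(n, 0.82, 0.07))
  diet_quality <- stats::rnorm(n)
  med_chol <- stats::runif(n) < 0.12
  med_bp <- stats::runif(n) < 0.14
  med_insulin <- stats::runif(n) < 0.01
  centre <- sample(sprintf("centre%02d", 1:22), n, TRUE)

  malabsorption <- stats::runif(n) < 0.005
  diabetes <- stats::runif(n) < 0.045
  prior_cvd_cancer <- stats::runif(n) < 0.10
  weight_loss <- stats::runif(n) < 0.02
  diet_not_typical <- stats::runif(n) < 0.08

  baseline <- as.Date("2009-04-01") + floor(stats::runif(n, 0, 540))
  n_recalls <- sample.int(5L, n, replace = TRUE, prob = config$recall_probs)
  last_date <- baseline
  followup_dates <- as.Date("2011-02-01") + floor(stats::runif(n, 0, 480))
  last_date[n_recalls > 1L] <- followup_dates[n_recalls > 1L]

  # sprinkle missingness for the exclusion machinery
  mp <- config$missing_prob
  if (mp > 0) {
    met[stats::runif(n) < mp] <- NA
    smoking[stats::runif(n) < mp] <- NA
    ethnicity[stats::runif(n) < mp] <- NA
    gen_health[stats::runif(n) < mp] <- NA
    qualification[stats::runif(n) < mp] <- NA
    townsend[stats::runif(n) < mp] <- NA
    bmi[stats::runif(n) < mp] <- NA
    sbp[stats::runif(n) < mp] <- NA
  }

  participants <- data.frame(
    participant_id = pid, sex = sex, age_years = age, height_m = height,
    weight_kg = weight, bmi_kg_m2 = bmi, sbp_mmHg = sbp,
    smoking_status = smoking, alcohol_g_day = alcohol, ethnicity = ethnicity,
    general_health = gen_health, qualification = qualification,
    psychiatric_history = psych, income_band = income, met_per_week = met,
    townsend = townsend, whr = whr, diet_quality = diet_quality,
    med_cholesterol = med_chol, med_blood_pressure = med_bp,
    med_insulin = med_insulin, centre = centre,
    malabsorption = malabsorption, diabetes = diabetes,
    prior_cvd_cancer = prior_cvd_cancer,
    unintentional_weight_loss = weight_loss,
    diet_not_typical = diet_not_typical,
    baseline_date = baseline, last_assessment_date = last_date,
    n_recalls = n_recalls, stringsAsFactors = FALSE)

  items <- names(cat$truth$consume_prob)
  cp <- cat$truth$consume_prob
  rec_list <- vector("list", n)
  for (i in seq_len(n)) {
    recs <- vector("list", n_recalls[i])
    for (r in seq_len(n_recalls[i])) {
      consumed <- items[stats::runif(length(items)) < cp]
      if (!length(consumed)) consumed <- sample(items, 1L)
      recs[[r]] <- data.frame(
        participant_id = pid[i], recall_index = r,
        recall_date = as.character(if (r == 1L) baseline[i] else
          last_date[i] - (n_recalls[i] - r) * 30L),
        item_id = consumed,
        n_portions = sample(1:3, length(consumed), TRUE,
                            prob = c(0.7, 0.2, 0.1)),
        stringsAsFactors = FALSE)
    }
    rec_list[[i]] <- do.call(rbind, recs)
  }
  recalls <- do.call(rbind, rec_list)

  list(participants = participants, recalls = recalls,
       truth = truth_profiles(recalls, cat$truth))
}

#' True exposure-log-hazard curve of a simulation config
#'
#' "null" is flat; "linear" has slope beta per exposure unit; "jshape" is a
#' smooth piecewise-quadratic with its minimum at \code{nadir} and separate
#' left/right curvatures (J-shape: shallow below the nadir, steeper above).
#'
#' @param config a \code{\link{sim_config}}.
#' @param x exposure values.
#' @return numeric log-hazard contributions (arbitrary additive constant).
#' @export
true_eta <- function(config, x) {
  tr <- config$truth
  switch(tr$type,
         null = rep(0, length(x)),
         linear = tr$beta * x,
         jshape = ifelse(x < tr$nadir, tr$a_left * (x - tr$nadir)^2,
                         tr$a_right * (x - tr$nadir)^2),
         stop("unknown truth type: ", tr$type))
}

#' Generate Weibull proportional-hazards survival outcomes
#'
#' Event times are drawn by inverse transform from a Weibull baseline scaled
#' by exp(eta_true(exposure) + covariate effects); censoring is the earlier
#' of random loss to follow-up and the administrative cutoff.
#'
#' @param config a \code{\link{sim_config}}.
#' @param exposure per-participant exposure values (e.g. UPF \%TFI).
#' @param eta_cov optional extra per-participant log-hazard (covariate
#'   effects); default 0.
#' @param entry_date per-participant entry dates (defaults to 2010-06-01).
#' @return data.frame(time_years, event, death_date, lost_date, eta_true).
#' @export
gen_survival <- function(config, exposure, eta_cov = 0,
                         entry_date = as.Date("2010-06-01")) {
  set.seed(config$seed + 3L)
  n <- length(exposure)
  eta <- true_eta(config, exposure) + rep_len(eta_cov, n)
  eta <- eta - mean(eta)
  tr <- config$truth
  u <- stats::runif(n)
  t_event <- tr$weibull_scale * (-log(u) / exp(eta))^(1 / tr$weibull_shape)
  entry <- rep_len(as.Date(entry_date), n)
  admin_years <- as.numeric(config$cutoff_date - entry) / 365.25
  t_loss <- if (tr$loss_rate > 0) stats::rexp(n, tr$loss_rate) else rep(Inf, n)
  t_cens <- pmin(t_loss, admin_years)
  event <- as.integer(t_event <= t_cens)
  time_years <- pmin(t_event, t_cens)
  data.frame(
    time_years = time_years, event = event,
    death_date = entry + ifelse(event == 1L, round(t_event * 365.25), NA),
    lost_date = entry + ifelse(event == 0L & t_loss < admin_years,
                               round(t_loss * 365.25), NA),
    eta_true = eta)
}
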