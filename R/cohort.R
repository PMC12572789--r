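#' Henry (Oxford) basal-metabolic-rate coefficient table
#'
#' Weight-and-height Oxford equations, kcal/day, with weight in kg and height
#' in metres: BMR = a*weight + b*height + c per sex and age band. The table is
#' an editable config; these defaults are the standard adult Oxford values.
#'
#' @return data.frame with columns sex, age_min, age_max, a, b, c.
#' @export
oxford_bmr_coefficients <- function() {
  data.frame(
    sex     = c("male", "male", "male", "female", "female", "female"),
    age_min = c(18, 30, 60, 18, 30, 60),
    age_max = c(30, 60, Inf, 30, 60, Inf),
    a = c(14.4, 11.4, 11.4, 10.4, 8.18, 8.52),
    b = c(313, 540, 540, 615, 502, 421),
    c = c(113, -137, -256, -282, -11.6, 10.7),
    stringsAsFactors = FALSE
  )
}

#' Basal metabolic rate (Oxford equation)
#'
#' @param sex "male"/"female" (vectorized).
#' @param age_years age in years.
#' @param weight_kg body weight in kg.
#' @param height_m height in metres.
#' @param coefficients coefficient table as from
#'   \code{\link{oxford_bmr_coefficients}} (editable).
#' @return BMR in kcal/day.
#' @export
oxford_bmr <- function(sex, age_years, weight_kg, height_m,
                       coefficients = oxford_bmr_coefficients()) {
  n <- max(length(sex), length(age_years), length(weight_kg), length(height_m))
  sex <- tolower(rep_len(as.character(sex), n))
  age_years <- rep_len(age_years, n)
  weight_kg <- rep_len(weight_kg, n)
  height_m <- rep_len(height_m, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    row <- which(coefficients$sex == sex[i] &
                   age_years[i] >= coefficients$age_min &
                   age_years[i] < coefficients$age_max)
    if (length(row) != 1L)
      stop("no BMR coefficient band for sex=", sex[i], ", age=", age_years[i])
    out[i] <- coefficients$a[row] * weight_kg[i] +
      coefficients$b[row] * height_m[i] + coefficients$c[row]
  }
  out
}

#' Energy-intake plausibility
#'
#' An intake is implausible if it is 0 kcal, below 1.1*BMR - 500 kcal, above
#' 2.5*BMR + 500 kcal, or above the population's 99.9th percentile
#' ("top 0.1\%"). The inequalities are strict: intakes exactly at a bound are
#' retained.
#'
#' @param total_kcal total daily energy intake (kcal), vectorized.
#' @param bmr_kcal basal metabolic rate (kcal/day), vectorized.
#' @param population_kcal energy intakes of the reference population used for
#'   the top-0.1\% cut (defaults to \code{total_kcal} itself).
#' @return logical: TRUE iff plausible.
#' @export
energy_plausible <- function(total_kcal, bmr_kcal,
                             population_kcal = total_kcal) {
  stopifnot(all(bmr_kcal > 0))
  p999 <- stats::quantile(population_kcal, 0.999, na.rm = TRUE, names = FALSE)
  !(total_kcal == 0 |
      total_kcal < 1.1 * bmr_kcal - 500 |
      total_kcal > 2.5 * bmr_kcal + 500 |
      total_kcal > p999)
}

exclusion_criteria_labels <- c(
  "1_missing_lifestyle",
  "2_implausible_event_data",
  "3_missing_socioeconomic",
  "4_missing_exam",
  "5_malabsorption",
  "6_diabetes",
  "7_implausible_energy"
)

#' Apply the seven cohort exclusion criteria
#'
#' Criteria are applied in their printed order with first-hit attribution:
#' (1) missing lifestyle factors (physical activity, smoking status),
#' (2) implausible event/censoring data, (3) missing socio-economic factors
#' (ethnicity, general health, qualification, Townsend index), (4) missing
#' exam parameters (BMI, SBP), (5) pre-existing malabsorption,
#' (6) pre-existing diabetes, (7) implausible energy intake.
#'
#' @param cohort participant data.frame (see \code{\link{gen_cohort}} for the
#'   column contract).
#' @param total_kcal per-participant total daily energy intake in kcal
#'   (from the exposure profiles), aligned with \code{cohort} rows.
#' @param cutoff_date administrative censoring date used to judge
#'   event-data plausibility.
#' @return list(cohort = retained rows, report = exclusion_report with
#'   per-criterion counts).
#' @export
apply_exclusions <- function(cohort, total_kcal,
                             cutoff_date = as.Date("2022-12-19")) {
  stopifnot(nrow(cohort) == length(total_kcal))
  n0 <- nrow(cohort)
  removed_at <- rep(NA_integer_, n0)

  miss <- function(x) is.na(x)
  hit <- function(which_crit, flag) {
    flag[is.na(flag)] <- FALSE
    idx <- flag & is.na(removed_at)
    removed_at[idx] <<- which_crit
  }

  hit(1L, miss(cohort$met_per_week) | miss(cohort$smoking_status))

  entry <- as.Date(cohort$last_assessment_date)
  death <- as.Date(cohort$death_date)
  bad_event <- miss(entry) |
    (!is.na(death) & death < entry) |
    (!is.na(death) & death > cutoff_date + 3650)
  hit(2L, bad_event)

  hit(3L, miss(cohort$ethnicity) | miss(cohort$general_health) |
        miss(cohort$qualification) | miss(cohort$townsend))
  hit(4L, miss(cohort$bmi_kg_m2) | miss(cohort$sbp_mmHg))
  hit(5L, cohort$malabsorption)
  hit(6L, cohort$diabetes)

  bmr <- oxford_bmr(cohort$sex, cohort$age_years, cohort$weight_kg,
                    cohort$height_m)
  plausible <- energy_plausible(total_kcal, bmr, population_kcal = total_kcal)
  hit(7L, !plausible)

  counts <- vapply(seq_len(7L), function(k) sum(removed_at == k, na.rm = TRUE),
                   integer(1))
  names(counts) <- exclusion_criteria_labels
  keep <- is.na(removed_at)
  report <- structure(list(initial_n = n0, removed = counts,
                           final_n = sum(keep)),
                      class = "exclusion_report")
  list(cohort = cohort[keep, , drop = FALSE], keep = keep, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusions: initial n =", x$initial_n, "\n")
  for (k in seq_along(x$removed))
    cat("  ", names(x$removed)[k], ": -", x$removed[k], "\n", sep = "")
  cat("  final n =", x$final_n, "\n")
  invisible(x)
}

#' Build a survival record per participant
#'
#' Follow-up runs from the last dietary assessment to death, loss to
#' follow-up, or the administrative cutoff, whichever comes first.
#'
#' @param entry_date last dietary assessment date (Date or ISO string).
#' @param death_date date of death or NA.
#' @param lost_date loss-to-follow-up date or NA.
#' @param cutoff_date administrative cutoff (default 2022-12-19).
#' @return data.frame(time_years, event) with event 1 = death, 0 = censored.
#' @export
build_survival <- function(entry_date, death_date = NA, lost_date = NA,
                           cutoff_date = as.Date("2022-12-19")) {
  entry <- as.Date(entry_date)
  death <- as.Date(death_date)
  lost <- as.Date(lost_date)
  n <- length(entry)
  death <- rep_len(death, n); lost <- rep_len(lost, n)
  cens <- pmin(ifelse(is.na(lost), as.numeric(cutoff_date), as.numeric(lost)),
               as.numeric(cutoff_date))
  dd <- as.numeric(death)
  if (any(!is.na(dd) & dd < as.numeric(entry)))
    stop("implausible event/censoring data: death before entry")
  event <- as.integer(!is.na(dd) & dd <= cens)
  end <- ifelse(event == 1L, dd, cens)
  time_years <- (end - as.numeric(entry)) / 365.25
  if (any(time_years < 0)) stop("implausible event/censoring data: negative follow-up")
  data.frame(time_years = time_years, event = event)
}

#' Derive the categorical analysis covariates
#'
#' Age, physical activity (MET), SBP and Townsend index are split at the
#' analysis cohort's own quintiles; alcohol uses the fixed bands <1, 1 to <8,
#' 8 to <16, >=16 g/day; BMI the fixed bands <18.5, 18.5 to <25, 25 to <30,
#' >=30 kg/m2. Sex, smoking status, ethnicity, general health, qualification,
#' psychiatric history and income are carried over as factors.
#'
#' @param cohort analysis cohort data.frame.
#' @return data.frame of factor covariates (one column per adjustment term).
#' @export
derive_covariates <- function(cohort) {
  stopifnot(nrow(cohort) > 0L)
  quint <- function(x, label) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, 0.2), na.rm = TRUE))
    if (length(br) < 6L)
      stop("fewer than 5 distinct quintile bins for ", label)
    cut(x, breaks = br, include.lowest = TRUE,
        labels = paste0("Q", 1:5))
  }
  out <- data.frame(
    age = quint(cohort$age_years, "age"),
    alcohol = cut(cohort$alcohol_g_day, c(-Inf, 1, 8, 16, Inf), right = FALSE,
                  labels = c("<1", "1 to <8", "8 to <16", ">=16")),
    bmi = cut(cohort$bmi_kg_m2, c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
              labels = c("<18.5", "18.5 to <25", "25 to <30", ">=30")),
    ethnicity = factor(cohort$ethnicity),
    general_health = factor(cohort$general_health,
                            levels = intersect(c("poor", "fair", "good", "excellent"),
                                               unique(cohort$general_health))),
    qualification = factor(cohort$qualification),
    psychiatric = factor(ifelse(cohort$psychiatric_history, "yes", "no")),
    income = factor(cohort$income_band),
    met = quint(cohort$met_per_week, "MET"),
    sbp = quint(cohort$sbp_mmHg, "SBP"),
    sex = factor(tolower(cohort$sex), levels = c("female", "male")),
    smoking = factor(cohort$smoking_status),
    townsend = quint(cohort$townsend, "Townsend")
  )
  droplevels(out)
}
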