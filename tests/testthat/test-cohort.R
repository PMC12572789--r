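test_that("Oxford BMR evaluates the configured linear form", {
  flat <- data.frame(sex = c("male", "female"), age_min = 0, age_max = Inf,
                     a = 0, b = 0, c = 1500)
  expect_equal(oxford_bmr("male", 50, 80, 1.8, flat), 1500)
  expect_equal(oxford_bmr("female", 70, 55, 1.6, flat), 1500)

  # hand evaluation of the shipped 30-60 male band: a*W + b*H + c
  co <- oxford_bmr_coefficients()
  row <- co[co$sex == "male" & co$age_min == 30, ]
  expect_equal(oxford_bmr("male", 55, 80, 1.80),
               row$a * 80 + row$b * 1.80 + row$c)
  expect_equal(oxford_bmr("male", 55, 0, 1.80), row$b * 1.80 + row$c)

  expect_error(oxford_bmr("male", 10, 40, 1.4), "no BMR coefficient band")
})

test_that("energy plausibility applies the BMR bounds strictly", {
  expect_false(energy_plausible(0, 1500, population_kcal = c(0, 2000, 2500)))
  # BMR 1500: bounds are (1150, 4250); 1200 is inside
  expect_true(energy_plausible(1200, 1500, population_kcal = rep(2000, 100)))
  expect_false(energy_plausible(1100, 1500, population_kcal = rep(2000, 100)))
  expect_false(energy_plausible(4300, 1500, population_kcal = rep(2000, 1000)))
  # values exactly at a bound are retained (strict inequalities)
  expect_true(energy_plausible(1.1 * 1500 - 500, 1500,
                               population_kcal = rep(2000, 100)))
  expect_true(energy_plausible(2.5 * 1500 + 500, 1500,
                               population_kcal = rep(6000, 100)))
  # top 0.1% of the population is excluded
  pop <- c(rep(2000, 1999), 9000)
  expect_false(energy_plausible(9000, 3000, population_kcal = pop))
  expect_true(energy_plausible(2000, 1500, population_kcal = pop))
})

test_that("exclusions follow printed order with first-hit attribution", {
  parts <- clean_participants(100, seed = 2)
  kcal <- rep(2200, 100)

  clean <- apply_exclusions(parts, kcal)
  expect_equal(clean$report$final_n, 100L)
  expect_true(all(clean$report$removed == 0L))

  planted <- parts
  planted$diabetes[1:5] <- TRUE
  res <- apply_exclusions(planted, kcal)
  expect_equal(unname(res$report$removed[["6_diabetes"]]), 5L)
  expect_equal(res$report$final_n, 95L)

  # violating (1) and (6) counts under (1) only
  both <- parts
  both$diabetes[7] <- TRUE
  both$met_per_week[7] <- NA
  res2 <- apply_exclusions(both, kcal)
  expect_equal(unname(res2$report$removed[["1_missing_lifestyle"]]), 1L)
  expect_equal(unname(res2$report$removed[["6_diabetes"]]), 0L)

  # count conservation
  set.seed(4)
  messy <- parts
  messy$smoking_status[runif(100) < 0.1] <- NA
  messy$bmi_kg_m2[runif(100) < 0.1] <- NA
  messy$malabsorption[runif(100) < 0.05] <- TRUE
  kcal2 <- kcal; kcal2[runif(100) < 0.1] <- 0
  res3 <- apply_exclusions(messy, kcal2)
  expect_equal(res3$report$initial_n,
               res3$report$final_n + sum(res3$report$removed))
  expect_equal(sum(res3$keep), res3$report$final_n)
})

test_that("survival records run from last assessment to first event", {
  one <- build_survival("2010-06-01", "2015-06-01")
  expect_equal(one$event, 1L)
  expect_equal(one$time_years, 5.0, tolerance = 1e-3)

  cens <- build_survival("2010-06-01")
  expect_equal(cens$event, 0L)
  expect_equal(cens$time_years,
               as.numeric(as.Date("2022-12-19") - as.Date("2010-06-01")) / 365.25)

  lost <- build_survival("2010-06-01", lost_date = "2012-06-01")
  expect_equal(lost$event, 0L)
  expect_equal(lost$time_years, 2.0, tolerance = 1e-3)

  # death after the cutoff is censored at the cutoff
  late <- build_survival("2010-06-01", "2023-06-01")
  expect_equal(late$event, 0L)

  expect_error(build_survival("2010-06-01", "2009-06-01"),
               "implausible event/censoring")

  # monotone in the cutoff
  t1 <- build_survival("2010-06-01", cutoff_date = as.Date("2020-12-19"))
  t2 <- build_survival("2010-06-01", cutoff_date = as.Date("2022-12-19"))
  expect_true(t2$time_years >= t1$time_years)
})

test_that("covariate bands match the printed cut points", {
  parts <- clean_participants(2000, seed = 6)
  parts$bmi_kg_m2[1] <- 24.9
  parts$alcohol_g_day[2] <- 16
  parts$alcohol_g_day[3] <- 0.99
  cv <- derive_covariates(parts)
  expect_equal(as.character(cv$bmi[1]), "18.5 to <25")
  expect_equal(as.character(cv$alcohol[2]), ">=16")
  expect_equal(as.character(cv$alcohol[3]), "<1")
  expect_true(all(table(cv$age) >= 1))

  # quintiles of a uniform sample split ~equally
  pu <- clean_participants(10000, seed = 7)
  pu$age_years <- runif(10000, 40, 75)
  cvu <- derive_covariates(pu)
  expect_true(all(abs(table(cvu$age) - 2000) <= 1))

  # quintile assignment is invariant under monotone rescaling
  pm <- pu
  pm$met_per_week <- exp(pu$met_per_week / 3000)
  expect_equal(as.integer(derive_covariates(pu)$met),
               as.integer(derive_covariates(pm)$met))

  few <- clean_participants(10, seed = 8)
  few$sbp_mmHg <- 120
  expect_error(derive_covariates(few), "quintile")
})
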