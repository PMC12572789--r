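base_inputs <- function(keys = "UPF") {
  c(small_study(), list(keys = keys, diagnose_ph = FALSE, grid_n = 128L))
}

test_that("all 17 variants are specified and modify one aspect each", {
  v <- sensitivity_variants()
  expect_length(v, 17L)
  expect_equal(vapply(v, `[[`, integer(1), "id"), setNames(1:17, names(v)))
  # one modifying aspect per variant (beyond id/label); the imputation
  # variants carry the relaxed-exclusion flag plus the imputer choice
  for (sp in v) {
    extra <- setdiff(names(sp), c("id", "label"))
    want <- if (isTRUE(sp$no_exclusions)) c("no_exclusions", "imputation")
    else extra[1]
    expect_setequal(extra, want)
  }
})

test_that("identity truncation reproduces the main analysis bit for bit", {
  base <- base_inputs()
  main <- run_variant(NULL, base)
  v15 <- run_variant(sensitivity_variants()$v15, base, max_products = 10L)
  v15$variant <- "main"
  expect_identical(main, v15)
})

test_that("landmark filtering is a no-op when no early deaths exist", {
  base <- base_inputs()
  # push every death past the 2-year landmark
  early <- !is.na(base$participants$death_date) &
    (as.numeric(base$participants$death_date -
                  base$participants$last_assessment_date) / 365.25) < 2
  base$participants$death_date[early] <-
    base$participants$last_assessment_date[early] + ceiling(2.2 * 365.25)
  main <- run_variant(NULL, base)
  v1 <- run_variant(sensitivity_variants()$v1, base)
  v1$variant <- "main"
  expect_identical(main, v1)
})

test_that("cumulative-intake variant analyses the specific-MUP sum", {
  base <- base_inputs()
  v16 <- run_variant(sensitivity_variants()$v16, base)
  expect_equal(v16$exposure, "cumulative")
  expect_equal(v16$status, "ok")
  # the exposure it models equals cumulative_intake of the profiles
  mli <- build_mli_table(base$cat$catalogue, base$lexicon,
                         gravity = base$cat$gravity,
                         fallback_g = base$cat$fallback_g)
  prof <- build_profiles(base$recalls, mli)
  expect_equal(prof$cumulative,
               unname(apply(prof$tfi, 1, cumulative_intake)))
})

test_that("imputation variants are delegated without a registered imputer", {
  base <- base_inputs()
  v10 <- run_variant(sensitivity_variants()$v10, base)
  expect_equal(v10$status, "delegated")
  v11 <- run_variant(sensitivity_variants()$v11, base)
  expect_equal(v11$status, "delegated")
  # a trivial complete-case imputer activates them
  imp <- function(parts) {
    for (nm in names(parts)) {
      if (is.numeric(parts[[nm]]))
        parts[[nm]][is.na(parts[[nm]])] <- mean(parts[[nm]], na.rm = TRUE)
      if (is.character(parts[[nm]]) && anyNA(parts[[nm]])) {
        tt <- table(parts[[nm]])
        parts[[nm]][is.na(parts[[nm]])] <- names(tt)[which.max(tt)]
      }
    }
    parts
  }
  v10b <- run_variant(sensitivity_variants()$v10, base, imputer = imp)
  expect_equal(v10b$status, "ok")
  # relaxing exclusions can only grow the cohort
  main <- run_variant(NULL, base)
  expect_gte(v10b$n, main$n)
})

test_that("covariate variants change exactly the intended model pieces", {
  base <- base_inputs()
  s <- small_study()
  mli <- build_mli_table(s$cat$catalogue, s$lexicon, gravity = s$cat$gravity,
                         fallback_g = s$cat$fallback_g)
  prof <- build_profiles(s$recalls, mli)
  parts <- s$participants[match(prof$participant_id,
                                s$participants$participant_id), ]
  keep <- apply_exclusions(parts, prof$total_energy_kj / 4.184)$keep
  covs <- derive_covariates(parts[keep, ])

  d7 <- mupsurv:::apply_covariate_delta(covs, parts[keep, ], "add_diet_quality")
  expect_true("diet_quality" %in% names(d7$covs))
  d8 <- mupsurv:::apply_covariate_delta(covs, parts[keep, ], "whr_height")
  expect_false("bmi" %in% names(d8$covs))
  expect_true(all(c("whr", "height") %in% names(d8$covs)))
  d9 <- mupsurv:::apply_covariate_delta(covs, parts[keep, ], "drop_energy")
  expect_true(d9$drop_energy)
  d13 <- mupsurv:::apply_covariate_delta(covs, parts[keep, ], "spline_bmi_sbp")
  expect_setequal(names(d13$extra_splines), c("bmi", "sbp"))
  expect_false(any(c("bmi", "sbp") %in% names(d13$covs)))

  # dropping energy removes exactly one spline term from the design
  surv <- build_survival(parts$last_assessment_date[keep],
                         parts$death_date[keep], parts$lost_date[keep])
  f_full <- fit_exposure_mortality(surv$time_years, surv$event,
                                   prof$tfi[keep, "UPF"],
                                   energy = prof$total_energy_kj[keep],
                                   covariates = covs, diagnose_ph = FALSE,
                                   grid_n = 64L)
  f_noe <- fit_exposure_mortality(surv$time_years, surv$event,
                                  prof$tfi[keep, "UPF"], energy = NULL,
                                  covariates = covs, diagnose_ph = FALSE,
                                  grid_n = 64L)
  expect_setequal(names(f_full$fit$terms), c("exposure", "energy"))
  expect_setequal(names(f_noe$fit$terms), "exposure")
  expect_equal(ncol(f_full$fit$X) - ncol(f_noe$fit$X), 7L)
})

test_that("the results summary counts significance and applies family BH", {
  base <- base_inputs(keys = c("UPF", "category:flavour",
                               "category:sweetener", "flavour", "lactose"))
  main <- run_variant(NULL, base)
  res <- structure(main, class = c("mup_results", "data.frame"))
  summ <- summarize_results(res)
  expect_setequal(summ$per_exposure$exposure, base$keys)
  expect_true(all(summ$per_exposure$n_run == 1L))
  # single-column matrix: summary equals that column
  expect_equal(summ$per_exposure$n_significant,
               as.integer(main$significant[match(summ$per_exposure$exposure,
                                                 main$exposure)]))
  # BH-adjusted significance never exceeds the unadjusted flags; adjustment
  # applies to the category and specific-marker families (not UPF itself)
  bh <- summ$main_bh[!is.na(summ$main_bh$p_bh), ]
  raw <- main$significant[match(bh$exposure, main$exposure)]
  expect_true(all(!bh$significant_bh | raw))
  expect_true(all(bh$p_bh >= bh$p_min - 1e-12))
  expect_true(is.na(summ$main_bh$p_bh[summ$main_bh$exposure == "UPF"]))
})
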