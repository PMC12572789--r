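#' The 17 sensitivity-analysis variants
#'
#' Each variant modifies exactly one aspect of the main analysis:
#' cohort filters (1-5), first-recall exposure (6), covariate changes
#' (7-9, 12-14), relaxed exclusions with pluggable imputation (10-11),
#' truncated-product MLI (15), cumulative specific-MUP exposure (16), and
#' Benjamini-Hochberg adjustment of the result matrix (17).
#'
#' @return named list of variant specs ("v1".."v17").
#' @export
sensitivity_variants <- function() {
  v <- function(id, label, ...) c(list(id = id, label = label), list(...))
  list(
    v1 = v(1L, "landmark: exclude follow-up < 2 years",
           filter = function(parts, surv, prof) surv$time_years >= 2),
    v2 = v(2L, "exclude unintentional weight loss",
           filter = function(parts, surv, prof) !parts$unintentional_weight_loss),
    v3 = v(3L, "exclude non-typical diet reports",
           filter = function(parts, surv, prof) !parts$diet_not_typical),
    v4 = v(4L, "exclude single-recall participants",
           filter = function(parts, surv, prof) parts$n_recalls > 1L),
    v5 = v(5L, "exclude prior CVD/cancer",
           filter = function(parts, surv, prof) !parts$prior_cvd_cancer),
    v6 = v(6L, "first recall only", exposure_mode = "first_recall"),
    v7 = v(7L, "adjust for diet quality", covariate_delta = "add_diet_quality"),
    v8 = v(8L, "WHR + height instead of BMI", covariate_delta = "whr_height"),
    v9 = v(9L, "drop energy intake", covariate_delta = "drop_energy"),
    v10 = v(10L, "no exclusions, kNN imputation", no_exclusions = TRUE,
            imputation = "knn"),
    v11 = v(11L, "no exclusions, random-forest imputation",
            no_exclusions = TRUE, imputation = "rf"),
    v12 = v(12L, "adjust for cardiometabolic medication",
            covariate_delta = "add_medications"),
    v13 = v(13L, "BMI and SBP as penalized splines",
            covariate_delta = "spline_bmi_sbp"),
    v14 = v(14L, "adjust for assessment centre", covariate_delta = "add_centre"),
    v15 = v(15L, "MLI from first k products", max_products = 8L),
    v16 = v(16L, "cumulative specific MUP intake", use_cumulative = TRUE),
    v17 = v(17L, "Benjamini-Hochberg FDR adjustment", adjustment = "bh")
  )
}

apply_covariate_delta <- function(covs, parts_kept, delta) {
  extra_splines <- NULL
  drop_energy <- FALSE
  if (!is.null(delta)) {
    if (delta == "add_diet_quality") covs$diet_quality <- parts_kept$diet_quality
    if (delta == "whr_height") {
      covs$bmi <- NULL
      q5 <- function(x) cut(x, unique(stats::quantile(x, seq(0, 1, 0.2))),
                            include.lowest = TRUE, labels = paste0("Q", 1:5))
      covs$whr <- q5(parts_kept$whr)
      covs$height <- q5(parts_kept$height_m)
    }
    if (delta == "drop_energy") drop_energy <- TRUE
    if (delta == "add_medications") {
      covs$med_cholesterol <- factor(parts_kept$med_cholesterol)
      covs$med_blood_pressure <- factor(parts_kept$med_blood_pressure)
      covs$med_insulin <- factor(parts_kept$med_insulin)
    }
    if (delta == "spline_bmi_sbp") {
      covs$bmi <- NULL; covs$sbp <- NULL
      extra_splines <- list(bmi = parts_kept$bmi_kg_m2,
                            sbp = parts_kept$sbp_mmHg)
    }
    if (delta == "add_centre") covs$centre <- factor(parts_kept$centre)
  }
  list(covs = covs, extra_splines = extra_splines, drop_energy = drop_energy)
}

#' Run one sensitivity variant (or the main analysis)
#'
#' Re-runs the full pipeline — MLI table, exposure profiles, exclusions,
#' survival construction, covariate derivation, spline Cox fits, HR curves —
#' under the given variant spec. \code{spec = NULL} (or the identity variant
#' 15 with \code{max_products = 10}) is the main analysis. Variants 10-11
#' require a registered imputer (\code{imputer} is a function(data.frame) ->
#' data.frame); without one they return a "delegated" status column rather
#' than failing.
#'
#' @param spec one element of \code{\link{sensitivity_variants}} or NULL.
#' @param base study inputs as from \code{\link{gen_study}}, plus analysis
#'   settings: \code{keys} (exposure keys to analyse), optional
#'   \code{df_target}, \code{diagnose_ph}, \code{cutoff_date},
#'   \code{grid_n}.
#' @param max_products overrides the spec's product truncation (variant 15
#'   is run at 8, 6 and 4).
#' @param imputer optional imputation hook for variants 10-11.
#' @return data.frame: one row per exposure key with p_linear, p_nonlinear,
#'   significant, nadir_x, hr_p99, slope, edf_exposure, n, n_event, status.
#' @export
run_variant <- function(spec, base, max_products = NULL, imputer = NULL) {
  keys <- base$keys %||% "UPF"
  variant_id <- if (is.null(spec)) "main" else paste0("v", spec$id)
  mk_row <- function(key, status, fitres = NULL, n = NA, n_event = NA) {
    if (is.null(fitres)) {
      data.frame(variant = variant_id, exposure = key, status = status,
                 p_linear = NA_real_, p_nonlinear = NA_real_,
                 significant = NA, nadir_x = NA_real_, hr_p99 = NA_real_,
                 slope = NA_real_, edf_exposure = NA_real_,
                 n = n, n_event = n_event, stringsAsFactors = FALSE)
    } else {
      eff <- fitres$effects[fitres$effects$term == "exposure", ]
      hr99 <- hr_at(fitres$curve, fitres$curve$p99)$hr
      data.frame(variant = variant_id, exposure = key, status = status,
                 p_linear = eff$p_linear, p_nonlinear = eff$p_nonlinear,
                 significant = eff$p_linear < 0.05 | eff$p_nonlinear < 0.05,
                 nadir_x = fitres$curve$nadir_x, hr_p99 = hr99,
                 slope = eff$slope,
                 edf_exposure = fitres$fit$edf[["exposure"]],
                 n = fitres$fit$n, n_event = fitres$fit$n_event,
                 stringsAsFactors = FALSE)
    }
  }

  if (!is.null(spec) && isTRUE(spec$no_exclusions) && is.null(imputer)) {
    return(do.call(rbind, lapply(keys, mk_row, status = "delegated")))
  }

  mp <- max_products %||% spec$max_products %||% 10L
  mode <- spec$exposure_mode %||% "mean_over_recalls"
  cutoff <- base$cutoff_date %||% as.Date("2022-12-19")

  mli <- build_mli_table(base$cat$catalogue, base$lexicon, max_products = mp,
                         gravity = base$cat$gravity,
                         fallback_g = base$cat$fallback_g)
  prof <- build_profiles(base$recalls, mli, mode = mode)
  parts <- base$participants[match(prof$participant_id,
                                   base$participants$participant_id), ]
  total_kcal <- prof$total_energy_kj / 4.184

  if (!is.null(spec) && isTRUE(spec$no_exclusions)) {
    parts <- imputer(parts)
    keep <- rep(TRUE, nrow(parts))
  } else {
    excl <- apply_exclusions(parts, total_kcal, cutoff_date = cutoff)
    keep <- excl$keep
  }
  parts <- parts[keep, , drop = FALSE]
  tfi <- prof$tfi[keep, , drop = FALSE]
  cum <- prof$cumulative[keep]
  energy <- prof$total_energy_kj[keep]

  surv <- build_survival(parts$last_assessment_date, parts$death_date,
                         parts$lost_date, cutoff_date = cutoff)

  if (!is.null(spec) && !is.null(spec$filter)) {
    f <- spec$filter(parts, surv, tfi)
    f[is.na(f)] <- FALSE
    parts <- parts[f, , drop = FALSE]; surv <- surv[f, , drop = FALSE]
    tfi <- tfi[f, , drop = FALSE]; cum <- cum[f]; energy <- energy[f]
  }

  covs <- derive_covariates(parts)
  delta <- apply_covariate_delta(covs, parts,
                                 if (is.null(spec)) NULL else spec$covariate_delta)

  if (!is.null(spec) && isTRUE(spec$use_cumulative)) keys <- "cumulative"

  rows <- lapply(keys, function(key) {
    expo <- if (identical(key, "cumulative")) cum else tfi[, key]
    tryCatch({
      fr <- fit_exposure_mortality(
        surv$time_years, surv$event, expo,
        energy = if (delta$drop_energy) NULL else energy,
        covariates = delta$covs, extra_splines = delta$extra_splines,
        df_target = base$df_target %||% 4,
        diagnose_ph = base$diagnose_ph %||% TRUE,
        grid_n = base$grid_n %||% 512L)
      mk_row(key, "ok", fr)
    }, error = function(e) mk_row(key, paste0("failed: ", conditionMessage(e)),
                                  n = nrow(parts), n_event = sum(surv$event)))
  })
  do.call(rbind, rows)
}

#' Run the main analysis and a set of sensitivity variants
#'
#' @param base study inputs (see \code{\link{run_variant}}).
#' @param variants which variants to run (default all 17).
#' @param imputer optional imputation hook for variants 10-11.
#' @return long data.frame of result cells, class \code{mup_results}.
#' @export
run_sensitivity <- function(base, variants = sensitivity_variants(),
                            imputer = NULL) {
  out <- list(run_variant(NULL, base))
  for (sp in variants) {
    if (!is.null(sp$max_products)) {
      for (k in c(8L, 6L, 4L)) {
        col <- run_variant(sp, base, max_products = k)
        col$variant <- paste0("v", sp$id, "_k", k)
        out[[length(out) + 1L]] <- col
      }
    } else {
      out[[length(out) + 1L]] <- run_variant(sp, base, imputer = imputer)
    }
  }
  structure(do.call(rbind, out), class = c("mup_results", "data.frame"))
}

#' Summarize a results matrix across variants
#'
#' Per exposure: how many analysis columns ran and how many were significant
#' (linear or non-linear p < 0.05 before adjustment). On the main column,
#' Benjamini-Hochberg adjustment is applied separately to the MUP-category
#' family and the specific-MUP family, flagging FDR-adjusted p < 0.05.
#'
#' @param results a \code{mup_results} data.frame (long form).
#' @return list(per_exposure, main_bh).
#' @export
summarize_results <- function(results) {
  stopifnot(nrow(results) >= 1L)
  ok <- results[results$status == "ok", , drop = FALSE]
  per_exposure <- do.call(rbind, lapply(split(ok, ok$exposure), function(d) {
    data.frame(exposure = d$exposure[1],
               n_run = nrow(d),
               n_significant = sum(d$significant, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  main <- ok[ok$variant == "main", , drop = FALSE]
  if (nrow(main) == 0L)
    return(list(per_exposure = per_exposure, main_bh = NULL))
  main$p_min <- pmin(main$p_linear, main$p_nonlinear)
  is_cat <- grepl("^category:", main$exposure)
  is_specific <- !is_cat & !main$exposure %in% c("UPF", "cumulative")
  main$p_bh <- NA_real_
  if (any(is_cat)) main$p_bh[is_cat] <- bh_adjust(main$p_min[is_cat])
  if (any(is_specific))
    main$p_bh[is_specific] <- bh_adjust(main$p_min[is_specific])
  main$significant_bh <- main$p_bh < 0.05
  list(per_exposure = per_exposure,
       main_bh = main[, c("exposure", "p_min", "p_bh", "significant_bh")])
}
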