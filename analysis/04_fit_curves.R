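#!/usr/bin/env Rscript
# 04 -- Penalized spline Cox models and nadir-rescaled HR curves.
#
# For UPF and each of the nine MUP categories: Cox model with the exposure
# and total energy intake as penalized cubic splines (8 base functions, 12
# knots, target 4 effective df), adjusted for the categorical covariates;
# scaled-Schoenfeld PH diagnosis with Holm-adjusted stratification (single
# pass); linear/non-linear effect split; HR curve on [0, p99] rescaled to 1
# at the HR-nadir.
#
# Outputs: results/effects.csv, results/curves/<exposure>.csv,
# results/figures/hr_curves.pdf.

suppressMessages(library(mupsurv))

analysis <- read.csv("results/analysis.csv", check.names = FALSE,
                     stringsAsFactors = FALSE)
dir.create("results/curves", recursive = TRUE, showWarnings = FALSE)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

cov_names <- c("age", "alcohol", "bmi", "ethnicity", "general_health",
               "qualification", "psychiatric", "income", "met", "sbp",
               "sex", "smoking", "townsend")
covs <- analysis[cov_names]
covs[] <- lapply(covs, factor)

keys <- c("UPF", paste0("category:", default_lexicon()$categories))
rows <- list()
pdf("results/figures/hr_curves.pdf", width = 10, height = 8)
par(mfrow = c(2, 5), mar = c(4, 4, 2, 1))
for (key in keys) {
  expo <- analysis[[paste0("tfi:", key)]]
  res <- tryCatch(
    fit_exposure_mortality(analysis$time_years, analysis$event, expo,
                           energy = analysis$energy_kj, covariates = covs,
                           diagnose_ph = TRUE),
    error = function(e) NULL)
  if (is.null(res)) {
    cat(sprintf("%-22s fit failed (degenerate exposure?)\n", key))
    next
  }
  eff <- res$effects[res$effects$term == "exposure", ]
  crv <- res$curve
  rows[[key]] <- data.frame(
    exposure = key, n = res$fit$n, n_event = res$fit$n_event,
    edf = unname(res$fit$edf[["exposure"]]),
    slope = eff$slope, p_linear = eff$p_linear,
    p_nonlinear = eff$p_nonlinear,
    nadir_x = crv$nadir_x, p99 = crv$p99,
    hr_p99 = hr_at(crv, crv$p99)$hr,
    strata = paste(res$strata_set, collapse = "+"))
  write.csv(crv$curve, sprintf("results/curves/%s.csv",
                               gsub("[^a-z0-9]+", "_", tolower(key))),
            row.names = FALSE)
  with(crv$curve, {
    plot(x, hr, type = "l", log = "y", ylim = range(c(lo, hi)),
         xlab = "%TFI", ylab = "HR (nadir = 1)", main = key, lwd = 2)
    lines(x, lo, lty = 2); lines(x, hi, lty = 2)
    abline(h = 1, col = "grey60")
    points(crv$nadir_x, 1, pch = 19)
  })
  cat(sprintf("%-22s nadir %5.1f %%TFI  p_lin %.2g  p_nonlin %.2g  %s\n",
              key, crv$nadir_x, eff$p_linear, eff$p_nonlinear,
              if (nzchar(rows[[key]]$strata))
                paste("stratified:", rows[[key]]$strata) else ""))
}
dev.off()

effects <- do.call(rbind, rows)
write.csv(effects, "results/effects.csv", row.names = FALSE)
cat(sprintf("\n%d of %d exposures significant (linear or non-linear p < 0.05).\n",
            sum(effects$p_linear < 0.05 | effects$p_nonlinear < 0.05),
            nrow(effects)))

# recovery check against the simulation's known truth
truth <- jsonlite::read_json("results/sim/truth.json", simplifyVector = TRUE)
true_nadir <- truth$truth_curve$nadir
upf <- analysis[["tfi:UPF"]]
cat(sprintf(paste0(
  "UPF truth check: true nadir %.0f %%TFI, estimated %.1f; %.0f%% of the cohort\n",
  "and %d deaths lie below the true nadir. With little mass on the left limb\n",
  "the fitted curve is effectively monotone and the nadir collapses to the\n",
  "boundary; the package's recovery simulations (n = 10,000, exposure centred\n",
  "near the nadir) quantify when the nadir is identifiable.\n"),
  true_nadir, effects$nadir_x[effects$exposure == "UPF"],
  100 * mean(upf < true_nadir),
  sum(analysis$event[upf < true_nadir])))
cat("Wrote results/effects.csv, results/curves/, results/figures/hr_curves.pdf\n")
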