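#!/usr/bin/env Rscript
# 01 -- Generate the synthetic study.
#
# Emulates the four pipeline inputs with known ground truth: a 238-item
# product catalogue (ingredient texts, portions, energies), 1-5 dietary
# recalls for 5,000 participants, a Table-1-like covariate panel, and
# Weibull survival times driven by a J-shaped true exposure-log-hazard
# curve with its nadir at 18 %TFI.
#
# Outputs under results/sim/: products.csv, recalls.csv, cohort.csv,
# truth.json (true MLIs, true %TFI, true curve parameters).

suppressMessages(library(mupsurv))

seed <- 20260926L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)   # defaults: 238 items, 5,000 participants
study <- gen_study(cfg)

write.csv(study$cat$catalogue, file.path(out_dir, "products.csv"),
          row.names = FALSE)
write.csv(study$recalls, file.path(out_dir, "recalls.csv"), row.names = FALSE)
write.csv(study$participants, file.path(out_dir, "cohort.csv"),
          row.names = FALSE)
jsonlite::write_json(
  list(seed = seed,
       truth_curve = cfg$truth,
       gravity = as.list(study$cat$gravity),
       fallback_g = as.list(study$cat$fallback_g),
       true_mli = as.data.frame(study$truth$catalogue$mli),
       true_tfi = data.frame(participant_id = study$truth$participant_id,
                             upf_tfi = study$truth$tfi[, "UPF"])),
  file.path(out_dir, "truth.json"), digits = NA)

n_death <- sum(!is.na(study$participants$death_date))
cat(sprintf("Generated %d products for %d items; %d recalls; %d participants (%d deaths).\n",
            nrow(study$cat$catalogue), cfg$n_items, nrow(study$recalls),
            nrow(study$participants), n_death))
cat(sprintf("True curve: J-shape, nadir %.0f %%TFI; mean true UPF intake %.1f %%TFI.\n",
            cfg$truth$nadir, mean(study$truth$tfi[, "UPF"])))
cat("Wrote", out_dir, "\n")
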