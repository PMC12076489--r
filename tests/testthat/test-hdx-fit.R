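test_that("deconvolution exactly inverts the noiseless forward model", {
  # all species counts used in the study: n = 6 and n = 9
  for (mono in c("BTA-(OH)3", "BTA-DNP3")) {
    m <- study_monomer(mono)
    row <- table1_row(mono)
    cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                               row$A_slow, penetration_rate = 0.3,
                               timepoints = c(0, 0.5, 2, 10, 70))
    s <- simulate_species_fractions(cfg)
    pat <- isotope_pattern(m$formula)
    ss <- spectra_from_fractions(s, pat)
    for (i in seq_along(ss$timepoints)) {
      f <- deconvolve_species(ss$spectra[[i]], pat, m)
      expect_lt(max(abs(f - s$fractions[i, ])), 1e-6)
    }
  }
})

test_that("deconvolution recovers constructed mixtures", {
  m <- study_monomer("BTA-(OH)3")
  pat <- isotope_pattern(m$formula)
  mk_series <- function(frac) structure(
    list(monomer = m, timepoints = 0, fractions = matrix(frac, nrow = 1)),
    class = "species_fraction_series")
  # pure 0D
  sp <- spectra_from_fractions(mk_series(c(1, rep(0, 6))), pat)$spectra[[1]]
  f <- deconvolve_species(sp, pat, m)
  expect_equal(unname(f), c(1, rep(0, 6)), tolerance = 1e-9)
  # 0.5/0.5 of 4D and 6D
  sp <- spectra_from_fractions(mk_series(c(0, 0, 0, 0, 0.5, 0, 0.5)),
                               pat)$spectra[[1]]
  f <- deconvolve_species(sp, pat, m)
  expect_equal(unname(f[5]), 0.5, tolerance = 1e-6)
  expect_equal(unname(f[7]), 0.5, tolerance = 1e-6)
  # 1% noise, 0.3/0.7 mixture recovered within 0.02 absolute (median
  # over replicates)
  errs <- vapply(1:10, function(sd) {
    sp <- spectra_from_fractions(mk_series(c(0.3, rep(0, 5), 0.7)), pat,
                                 noise_rel = 0.01, seed = sd)$spectra[[1]]
    f <- deconvolve_species(sp, pat, m)
    max(abs(f[c(1, 7)] - c(0.3, 0.7)))
  }, numeric(1))
  expect_lt(median(errs), 0.02)
  expect_error(deconvolve_species(data.frame(mz = 1, intensity = 0),
                                  pat, m), "all-zero")
})

test_that("charge-2 envelopes deconvolve as well", {
  m <- study_monomer("BTA-DNP3")
  row <- table1_row("BTA-DNP3")
  cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                             row$A_slow, timepoints = c(0, 1, 30))
  s <- simulate_species_fractions(cfg)
  pat <- isotope_pattern(m$formula)
  ss <- spectra_from_fractions(s, pat, charge = 2L)
  f <- deconvolve_species(ss$spectra[[3]], pat, m, charge = 2L)
  expect_lt(max(abs(f - s$fractions[3, ])), 1e-6)
})

test_that("fully_deuterated_curve extracts the nD percentage", {
  m <- study_monomer("BTA-(OH)3")
  fr <- matrix(0, 3, 7); fr[, 1] <- 1
  s <- structure(list(monomer = m, timepoints = c(0, 1, 2),
                      fractions = fr),
                 class = "species_fraction_series")
  expect_equal(fully_deuterated_curve(s)$percent_nd, c(0, 0, 0))
  s1 <- structure(list(monomer = m, timepoints = 5,
                       fractions = matrix(c(0.4, rep(0, 5), 0.6), 1)),
                  class = "species_fraction_series")
  crv <- fully_deuterated_curve(s1)
  expect_equal(nrow(crv), 1)
  expect_equal(crv$percent_nd, 60)
})

test_that("biexponential fit recovers generating parameters exactly at zero noise", {
  for (mono in c("BTA-(OH)3", "BTA-DNP3")) {
    row <- table1_row(mono)
    fit <- fit_biexponential(simulate_biexp_curve(row, noise_rel = 0))
    expect_lt(abs(fit$k_fast - row$k_fast) / row$k_fast, 1e-3)
    expect_lt(abs(fit$k_slow - row$k_slow) / row$k_slow, 1e-3)
    expect_lt(abs(fit$A_fast - row$A_fast) / row$A_fast, 1e-3)
    expect_lt(abs(fit$A_slow - row$A_slow) / row$A_slow, 1e-3)
    expect_true(fit$k_fast > fit$k_slow)
    expect_true(fit$converged)
  }
})

test_that("degenerate curves are handled: zero and single-exponential", {
  t <- default_hdx_timepoints()
  z <- fit_biexponential(data.frame(t_h = t, percent_nd = 0 * t))
  expect_equal(z$A_fast + z$A_slow, 0)
  expect_false(z$identifiable)
  # noiseless single exponential: one amplitude collapses to ~0
  y <- 60 * (1 - exp(-0.5 * t))
  f1 <- fit_biexponential(data.frame(t_h = t, percent_nd = y))
  amps <- sort(c(f1$A_fast, f1$A_slow))
  expect_lt(amps[1], 0.5)
  expect_equal(amps[2], 60, tolerance = 0.01)
  expect_error(fit_biexponential(data.frame(t_h = 1:3,
                                            percent_nd = c(1, 2, 3))),
               "5 timepoints")
  expect_error(fit_biexponential(data.frame(t_h = t,
                                            percent_nd = 0 * t + 150)),
               "\\[0, 100\\]")
})

test_that("median k_fast recovery at 2% noise stays within 10%", {
  # parameter-recovery property across both copolymer parameter rows
  for (mono in c("BTA-(OH)3", "BTA-DNP3")) {
    row <- table1_row(mono)
    kf <- vapply(1:20, function(sd)
      fit_biexponential(simulate_biexp_curve(row, noise_rel = 0.02,
                                             seed = sd))$k_fast,
      numeric(1))
    expect_lt(abs(median(kf) - row$k_fast) / row$k_fast, 0.1)
  }
})

test_that("eval_biexponential respects limits and the 70 h landmark", {
  row <- table1_row("BTA-DNP3")
  expect_equal(eval_biexponential(row, 0), 0)
  # printed as ~80% after 70 h
  expect_equal(eval_biexponential(row, 70), 79.27, tolerance = 0.001)
  expect_equal(eval_biexponential(row, 1e6), row$A_fast + row$A_slow,
               tolerance = 1e-9)
  tt <- seq(0, 100, by = 0.5)
  yy <- eval_biexponential(row, tt)
  expect_true(all(diff(yy) >= 0))
  expect_true(all(yy <= row$A_fast + row$A_slow + 1e-12))
  expect_error(eval_biexponential(row, -1), ">= 0")
})

test_that("intermediate species report solvent penetration", {
  m <- study_monomer("BTA-DNP3")
  row <- table1_row("BTA-DNP3")
  mk <- function(p) simulate_species_fractions(
    exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                        row$A_slow, penetration_rate = p,
                        timepoints = c(0, 0.5, 1, 1.5, 2, 10)))
  none <- intermediate_species_summary(mk(0))
  expect_equal(unname(none), c(0, 0))
  lo <- intermediate_species_summary(mk(0.2))
  hi <- intermediate_species_summary(mk(0.8))
  expect_true(all(hi >= lo))
  expect_gt(sum(hi), sum(lo))
  expect_error(intermediate_species_summary(mk(0.2), window = c(80, 90)),
               "window")
})

test_that("monomer comparison tabulates rates and ratios", {
  f_oh <- fit_biexponential(simulate_biexp_curve(table1_row("BTA-(OH)3"),
                                                 noise_rel = 0))
  f_dnp <- fit_biexponential(simulate_biexp_curve(table1_row("BTA-DNP3"),
                                                  noise_rel = 0))
  cmp <- compare_monomers(list("BTA-(OH)3" = f_oh, "BTA-DNP3" = f_dnp))
  r <- cmp$ratios
  ratio <- r$k_fast_ratio[r$numerator == "BTA-(OH)3"]
  expect_equal(ratio, 3.45 / 0.76, tolerance = 1e-2)
  same <- compare_monomers(list(a = f_oh, b = f_oh))
  expect_equal(same$ratios$k_fast_ratio, c(1, 1), tolerance = 1e-12)
  expect_error(compare_monomers(list(f_oh)), "at least 2")
})
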