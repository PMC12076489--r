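test_that("exchange config enforces its invariants", {
  m <- study_monomer("BTA-DNP3")
  expect_error(exchange_sim_config(m, 0.05, 0.76, 50, 10),
               "k_fast > k_slow")
  expect_error(exchange_sim_config(m, 1, 0.1, 80, 30), "<= 100")
  expect_error(exchange_sim_config(m, 1, 0.1, 50, 10,
                                   timepoints = c(2, 1)), "increasing")
})

test_that("species fractions start at outer-exchanged and sum to one", {
  for (mono in c("BTA-(OH)3", "BTA-DNP3")) {
    m <- study_monomer(mono)
    row <- table1_row(mono)
    cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                               row$A_slow, penetration_rate = 0.2)
    s <- simulate_species_fractions(cfg)
    expect_equal(rowSums(s$fractions), rep(1, length(cfg$timepoints)),
                 tolerance = 1e-12)
    # instantaneous outer exchange at t = 0
    expect_equal(unname(s$fractions[1, m$n_outer + 1]), 1)
    # fully-deuterated fraction non-decreasing in time
    expect_true(all(diff(s$fractions[, m$n_labile_total + 1]) >= -1e-12))
  }
})

test_that("without penetration the model reduces to the biexponential", {
  m <- study_monomer("BTA-DNP3")
  row <- table1_row("BTA-DNP3")
  cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                             row$A_slow, penetration_rate = 0)
  s <- simulate_species_fractions(cfg)
  nd <- 100 * unname(s$fractions[, m$n_labile_total + 1])
  expect_equal(nd, biexp_growth(cfg$timepoints, row$k_fast, row$k_slow,
                                row$A_fast, row$A_slow),
               tolerance = 1e-12)
  # t -> large limit approaches A_fast + A_slow
  cfg2 <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                              row$A_slow,
                              timepoints = c(0, 1e4))
  s2 <- simulate_species_fractions(cfg2)
  expect_equal(100 * unname(s2$fractions[2, 10]),
               row$A_fast + row$A_slow, tolerance = 1e-6)
  # intermediates only arise through the penetration channel
  expect_true(all(s$fractions[, m$n_labile_total] == 0))
})

test_that("fitted copolymer parameters put full deuteration near 80% at 70 h", {
  m <- study_monomer("BTA-DNP3")
  row <- table1_row("BTA-DNP3")
  cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                             row$A_slow, timepoints = c(0, 70))
  s <- simulate_species_fractions(cfg)
  expect_equal(100 * unname(s$fractions[2, 10]), 80, tolerance = 0.02)
})

test_that("spectra are shifted weighted patterns; noiseless is exact", {
  m <- study_monomer("BTA-(OH)3")
  pat <- isotope_pattern(m$formula)
  mt <- mass_table()
  # single pure species: spectrum equals the shifted pattern
  series <- structure(list(
    monomer = m, timepoints = 0,
    fractions = matrix(c(rep(0, 6), 1), nrow = 1)),
    class = "species_fraction_series")
  ss <- spectra_from_fractions(series, pat)
  sp <- ss$spectra[[1]]
  expect_equal(sp$mz, mz_for_charge(pat$mass + 6 * mt$dh_mass_diff, 1),
               tolerance = 1e-12)
  expect_equal(sp$intensity, pat$abundance, tolerance = 1e-12)
  # 50/50 mixture of 0D and nD equals the half-weighted sum of the two
  # pure envelopes (direct construction)
  mk <- function(frac) structure(
    list(monomer = m, timepoints = 0, fractions = matrix(frac, nrow = 1)),
    class = "species_fraction_series")
  sp2 <- spectra_from_fractions(mk(c(0.5, rep(0, 5), 0.5)),
                                pat)$spectra[[1]]
  p0 <- spectra_from_fractions(mk(c(1, rep(0, 6))), pat)$spectra[[1]]
  p6 <- spectra_from_fractions(mk(c(rep(0, 6), 1)), pat)$spectra[[1]]
  both <- rbind(p0, p6)
  both$intensity <- both$intensity / 2
  both <- both[order(both$mz), ]
  agg <- rowsum(both$intensity, round(both$mz * 1e6))
  expect_equal(sum(sp2$intensity), 1, tolerance = 1e-9)
  expect_equal(sp2$intensity, as.vector(agg), tolerance = 1e-9)
})

test_that("generators are seed-reproducible and seed-sensitive", {
  m <- study_monomer("BTA-DNP3")
  row <- table1_row("BTA-DNP3")
  cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                             row$A_slow)
  s <- simulate_species_fractions(cfg)
  pat <- isotope_pattern(m$formula)
  a <- spectra_from_fractions(s, pat, noise_rel = 0.02, seed = 11)
  b <- spectra_from_fractions(s, pat, noise_rel = 0.02, seed = 11)
  c <- spectra_from_fractions(s, pat, noise_rel = 0.02, seed = 12)
  expect_identical(a$spectra, b$spectra)
  expect_false(identical(a$spectra, c$spectra))
  c1 <- simulate_biexp_curve(row, noise_rel = 0.02, seed = 5)
  c2 <- simulate_biexp_curve(row, noise_rel = 0.02, seed = 5)
  expect_identical(c1, c2)
})

test_that("spectrum series round-trips through CSV", {
  m <- study_monomer("BTA-(OH)3")
  row <- table1_row("BTA-(OH)3")
  cfg <- exchange_sim_config(m, row$k_fast, row$k_slow, row$A_fast,
                             row$A_slow, timepoints = c(0, 1, 10))
  ss <- spectra_from_fractions(simulate_species_fractions(cfg),
                               isotope_pattern(m$formula))
  f <- tempfile(fileext = ".csv")
  write_hdx_spectra(ss, f)
  back <- read_hdx_spectra(f, monomer = m)
  expect_equal(back$timepoints, ss$timepoints)
  for (i in seq_along(ss$spectra))
    expect_equal(back$spectra[[i]]$intensity, ss$spectra[[i]]$intensity,
                 tolerance = 1e-12)
})
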