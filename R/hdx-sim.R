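#' Configuration for the two-pathway exchange simulator
#'
#' The generative model distinguishes three subpopulations of monomers
#' after dilution into D2O: a fast fraction (`A_fast` percent) whose
#' inner amides exchange all at once upon monomer escape at rate
#' `k_fast`, a slow fraction (`A_slow` percent) doing the same at
#' `k_slow`, and a remainder that is inert over the observation window.
#' Independently, solvent penetration into less ordered parts of the
#' stack exchanges the inner hydrogens of any not-yet-escaped monomer
#' one at a time at `penetration_rate`, producing the intermediate
#' (n-1)D, (n-2)D species. Outer hydrogens exchange instantaneously at
#' t = 0+.
#'
#' @param monomer A [monomer_spec()].
#' @param k_fast,k_slow Escape rate constants, 1/h; `k_fast > k_slow`.
#' @param A_fast,A_slow Subpopulation amplitudes in percent;
#'   `A_fast + A_slow <= 100`.
#' @param penetration_rate Per-hydrogen sequential exchange rate, 1/h.
#' @param timepoints Increasing sampling times in hours, first >= 0.
#' @param noise_rel Relative intensity noise s.d. used downstream by
#'   [spectra_from_fractions()].
#' @param seed Integer RNG seed for downstream stochastic steps.
#' @return Object of class `exchange_sim_config`.
#' @export
exchange_sim_config <- function(monomer, k_fast, k_slow, A_fast, A_slow,
                                penetration_rate = 0,
                                timepoints = default_hdx_timepoints(),
                                noise_rel = 0.02, seed = 1L) {
  stopifnot(inherits(monomer, "monomer_spec"))
  if (!(k_fast > k_slow && k_slow > 0))
    stop("require k_fast > k_slow > 0")
  if (A_fast < 0 || A_slow < 0 || A_fast + A_slow > 100)
    stop("require A_fast, A_slow >= 0 and A_fast + A_slow <= 100")
  if (penetration_rate < 0) stop("penetration_rate must be >= 0")
  if (is.unsorted(timepoints, strictly = TRUE) || timepoints[1] < 0)
    stop("timepoints must be strictly increasing, first >= 0")
  structure(list(monomer = monomer, k_fast = k_fast, k_slow = k_slow,
                 A_fast = A_fast, A_slow = A_slow,
                 penetration_rate = penetration_rate,
                 timepoints = timepoints, noise_rel = noise_rel,
                 seed = as.integer(seed)),
            class = "exchange_sim_config")
}

#' Simulate deuterated-species fractions over time
#'
#' Deterministic (noise-free) species-fraction kinetics under the
#' two-pathway model of [exchange_sim_config()]. A monomer that has
#' escaped is fully deuterated (nD). A monomer that has not escaped sits
#' at `n_outer + j` deuteriums, where j is the number of inner hydrogens
#' exchanged by the sequential penetration channel; with equal
#' per-hydrogen rate p, j follows the Erlang stage occupation
#' P(j; t) = (pt)^j e^(-pt) / j! for j < n_inner, with the final stage
#' absorbing. Escape and penetration act independently, so fractions sum
#' to one at every timepoint by construction.
#'
#' @param cfg An `exchange_sim_config`.
#' @return Object of class `species_fraction_series`: list with
#'   `monomer`, `timepoints` (h), and `fractions`, a length(t) x (n+1)
#'   matrix with columns `d0` ... `dn`.
#' @export
simulate_species_fractions <- function(cfg) {
  stopifnot(inherits(cfg, "exchange_sim_config"))
  n <- cfg$monomer$n_labile_total
  n_out <- cfg$monomer$n_outer
  n_in <- cfg$monomer$n_inner
  t <- cfg$timepoints
  frac <- matrix(0, nrow = length(t), ncol = n + 1,
                 dimnames = list(NULL, paste0("d", 0:n)))
  a_f <- cfg$A_fast / 100; a_s <- cfg$A_slow / 100
  a_0 <- 1 - a_f - a_s
  p <- cfg$penetration_rate
  for (i in seq_along(t)) {
    ti <- t[i]
    # probability of not-yet-escaped per subpopulation
    surv <- a_f * exp(-cfg$k_fast * ti) + a_s * exp(-cfg$k_slow * ti) + a_0
    escaped <- 1 - surv
    pj <- .erlang_stage_probs(p * ti, n_in)
    for (j in 0:n_in)
      frac[i, n_out + j + 1] <- frac[i, n_out + j + 1] + surv * pj[j + 1]
    frac[i, n + 1] <- frac[i, n + 1] + escaped
  }
  structure(list(monomer = cfg$monomer, timepoints = t, fractions = frac),
            class = "species_fraction_series")
}

# stage-occupation probabilities of a sequential j = 0..k chain with
# equal rates; x = rate * time; final stage absorbs the tail
.erlang_stage_probs <- function(x, k) {
  if (k == 0L) return(1)
  pj <- dpois(0:(k - 1), x)
  c(pj, max(0, 1 - sum(pj)))
}

#' Percent fully deuterated under the biexponential growth model
#'
#' y(t) = A_fast (1 - e^(-k_fast t)) + A_slow (1 - e^(-k_slow t)),
#' in percent. This is the closed form the species-fraction simulator
#' reduces to when the penetration channel is off, and the model fitted
#' to experimental full-deuteration curves.
#'
#' @param t Times in hours (>= 0).
#' @param k_fast,k_slow Rate constants, 1/h.
#' @param A_fast,A_slow Amplitudes, percent.
#' @return Percent fully deuterated at each `t`.
#' @export
biexp_growth <- function(t, k_fast, k_slow, A_fast, A_slow) {
  if (any(t < 0)) stop("t must be >= 0")
  A_fast * (1 - exp(-k_fast * t)) + A_slow * (1 - exp(-k_slow * t))
}

#' Simulate a noisy fully-deuterated-percent curve
#'
#' Generates parameter-recovery fixtures directly from the biexponential
#' closed form (no mechanistic detour, so recovery tests are free of
#' model mismatch), with multiplicative Gaussian noise.
#'
#' @param params List or one-row data.frame with `k_fast`, `k_slow`,
#'   `A_fast`, `A_slow` (e.g. a row of [exchange_parameter_table()]).
#' @param timepoints Times in hours.
#' @param noise_rel Relative noise s.d. (0 = noiseless).
#' @param seed Integer seed.
#' @return data.frame with columns `t_h` and `percent_nd`.
#' @export
simulate_biexp_curve <- function(params,
                                 timepoints = default_hdx_timepoints(),
                                 noise_rel = 0.02, seed = 1L) {
  y <- biexp_growth(timepoints, params$k_fast, params$k_slow,
                    params$A_fast, params$A_slow)
  if (noise_rel > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    y <- y * (1 + rnorm(length(y), sd = noise_rel))
  }
  data.frame(t_h = timepoints, percent_nd = pmax(y, 0))
}

#' Render mass spectra from species fractions
#'
#' Forward model for HDX envelope deconvolution: species j (j deuteriums
#' exchanged) contributes the monomer's natural isotope pattern shifted
#' by j * (m_D - m_H) / z, weighted by its fraction. Multiplicative
#' Gaussian noise of s.d. `noise_rel` is applied per peak intensity and
#' negative intensities are clamped to zero.
#'
#' @param series A `species_fraction_series`.
#' @param pattern An [isotope_pattern()] of the undeuterated monomer.
#' @param charge Positive integer charge state (protonated).
#' @param noise_rel Relative intensity noise s.d.
#' @param seed Integer seed.
#' @param mt Mass table.
#' @return List of class `hdx_spectrum_series`: `timepoints` and
#'   `spectra`, one data.frame (`mz`, `intensity`) per timepoint.
#' @export
spectra_from_fractions <- function(series, pattern, charge = 1L,
                                   noise_rel = 0, seed = 1L,
                                   mt = mass_table()) {
  stopifnot(inherits(series, "species_fraction_series"),
            inherits(pattern, "isotope_pattern"))
  if (nrow(pattern) == 0L) stop("empty isotope pattern")
  n <- series$monomer$n_labile_total
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  spectra <- lapply(seq_along(series$timepoints), function(i) {
    f <- series$fractions[i, ]
    stopifnot(abs(sum(f) - 1) < 1e-6)
    peaks <- do.call(rbind, lapply(0:n, function(j) {
      if (f[j + 1] <= 0) return(NULL)
      data.frame(
        mz = mz_for_charge(pattern$mass + j * mt$dh_mass_diff, charge,
                           mt = mt),
        intensity = f[j + 1] * pattern$abundance)
    }))
    peaks <- .merge_peaks(peaks)
    if (noise_rel > 0)
      peaks$intensity <- pmax(
        0, peaks$intensity * (1 + rnorm(nrow(peaks), sd = noise_rel)))
    peaks[order(peaks$mz), ]
  })
  structure(list(monomer = series$monomer, timepoints = series$timepoints,
                 charge = charge, spectra = spectra),
            class = "hdx_spectrum_series")
}

# co-add stick peaks closer than 1e-6 m/z
.merge_peaks <- function(peaks) {
  key <- round(peaks$mz / 1e-6)
  inten <- rowsum(peaks$intensity, key)
  mz <- rowsum(peaks$mz * peaks$intensity, key) / pmax(inten, .Machine$double.xmin)
  out <- data.frame(mz = as.vector(mz), intensity = as.vector(inten))
  rownames(out) <- NULL
  out
}

#' Write an HDX spectrum series to CSV
#'
#' Long format: `timepoint_h`, `mz`, `intensity`.
#'
#' @param ss An `hdx_spectrum_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hdx_spectra <- function(ss, path) {
  rows <- do.call(rbind, lapply(seq_along(ss$timepoints), function(i)
    cbind(timepoint_h = ss$timepoints[i], ss$spectra[[i]])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read an HDX spectrum series from CSV
#'
#' @param path CSV with columns `timepoint_h`, `mz`, `intensity`.
#' @param monomer Optional [monomer_spec()] to attach.
#' @param charge Charge state the spectra were recorded at.
#' @return An `hdx_spectrum_series`.
#' @export
read_hdx_spectra <- function(path, monomer = NULL, charge = 1L) {
  d <- utils::read.csv(path)
  stopifnot(all(c("timepoint_h", "mz", "intensity") %in% names(d)))
  tp <- sort(unique(d$timepoint_h))
  spectra <- lapply(tp, function(t) {
    s <- d[d$timepoint_h == t, c("mz", "intensity")]
    s[order(s$mz), ]
  })
  structure(list(monomer = monomer, timepoints = tp, charge = charge,
                 spectra = spectra), class = "hdx_spectrum_series")
}

# save/restore the global RNG state so generators are reproducible
# without clobbering the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}
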