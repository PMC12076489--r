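#' Deconvolve deuterated-species fractions from a mass spectrum
#'
#' Solves the non-negative least-squares problem
#' observed envelope ~ sum_j f_j * P_j, where P_j is the monomer's
#' natural isotope pattern shifted by j * (m_D - m_H) / z. Observed and
#' predicted stick peaks are aligned onto a common m/z grid by
#' centroid binning (`mz_tol` wide), and the recovered fractions are
#' normalized to sum one.
#'
#' @param spectrum data.frame with columns `mz`, `intensity`.
#' @param pattern [isotope_pattern()] of the undeuterated monomer.
#' @param spec [monomer_spec()] giving the species count n.
#' @param charge Positive integer charge state.
#' @param mz_tol Grid bin width in m/z units.
#' @param mt Mass table.
#' @return Numeric vector `d0` ... `dn` of fractions summing to 1.
#' @export
deconvolve_species <- function(spectrum, pattern, spec, charge = 1L,
                               mz_tol = 0.005, mt = mass_table()) {
  stopifnot(inherits(pattern, "isotope_pattern"),
            inherits(spec, "monomer_spec"))
  if (nrow(spectrum) == 0L || all(spectrum$intensity == 0))
    stop("all-zero spectrum")
  n <- spec$n_labile_total
  predicted <- lapply(0:n, function(j)
    data.frame(mz = mz_for_charge(pattern$mass + j * mt$dh_mass_diff,
                                  charge, mt = mt),
               abundance = pattern$abundance))
  env_lo <- min(predicted[[1]]$mz); env_hi <- max(predicted[[n + 1]]$mz)
  if (max(spectrum$mz) < env_lo - mz_tol ||
      min(spectrum$mz) > env_hi + mz_tol)
    stop("species envelope [", round(env_lo, 3), ", ", round(env_hi, 3),
         "] lies outside the spectrum m/z range")
  key_of <- function(mz) round(mz / mz_tol)
  obs_key <- key_of(spectrum$mz)
  grid <- sort(unique(c(obs_key, unlist(lapply(predicted,
                                               function(p) key_of(p$mz))))))
  b <- numeric(length(grid))
  idx <- match(obs_key, grid)
  b[sort(unique(idx))] <- rowsum(spectrum$intensity, idx)[, 1]
  A <- matrix(0, nrow = length(grid), ncol = n + 1)
  for (j in 0:n) {
    pidx <- match(key_of(predicted[[j + 1]]$mz), grid)
    A[sort(unique(pidx)), j + 1] <-
      rowsum(predicted[[j + 1]]$abundance, pidx)[, 1]
  }
  f <- pracma::lsqnonneg(A, b)$x
  if (sum(f) <= 0) stop("deconvolution returned an all-zero solution")
  f <- f / sum(f)
  setNames(f, paste0("d", 0:n))
}

#' Deconvolve a whole spectrum time series
#'
#' Applies [deconvolve_species()] per timepoint.
#'
#' @param ss An `hdx_spectrum_series`.
#' @param pattern,spec,mz_tol,mt See [deconvolve_species()].
#' @return A `species_fraction_series`.
#' @export
deconvolve_series <- function(ss, pattern, spec = ss$monomer,
                              mz_tol = 0.005, mt = mass_table()) {
  stopifnot(inherits(ss, "hdx_spectrum_series"))
  frac <- t(vapply(ss$spectra, function(s)
    deconvolve_species(s, pattern, spec, charge = ss$charge,
                       mz_tol = mz_tol, mt = mt),
    numeric(spec$n_labile_total + 1)))
  structure(list(monomer = spec, timepoints = ss$timepoints,
                 fractions = frac), class = "species_fraction_series")
}

#' Extract the fully-deuterated time course
#'
#' The percentage of nD species (all labile hydrogens exchanged) as a
#' function of time — the monomer-dynamicity readout.
#'
#' @param series A `species_fraction_series`.
#' @return data.frame with columns `t_h`, `percent_nd`.
#' @export
fully_deuterated_curve <- function(series) {
  stopifnot(inherits(series, "species_fraction_series"))
  n <- series$monomer$n_labile_total
  data.frame(t_h = series$timepoints,
             percent_nd = 100 * series$fractions[, n + 1])
}

#' Fit the two-process biexponential growth model
#'
#' Least-squares fit of y(t) = A_fast (1 - e^(-k_fast t)) +
#' A_slow (1 - e^(-k_slow t)) to a fully-deuterated-percent curve, with
#' amplitudes bounded in \[0, 100\] and positive rates. The amplitudes
#' are deliberately not constrained to sum to 100: an unexchanged
#' remainder within the observation window leaves the plateau below
#' 100%. Fitting uses bounded Levenberg-Marquardt with a multi-start
#' policy (rate scales seeded from the early-time slope and the tail),
#' keeping the best-RSS solution; the larger rate is labelled "fast"
#' (tie broken by amplitude).
#'
#' @param curve data.frame with columns `t_h` and `percent_nd`, at least
#'   5 timepoints spanning the fast and slow regimes.
#' @param n_starts Number of multi-start attempts.
#' @return Object of class `kinetic_fit`: `k_fast`, `k_slow` (1/h),
#'   `A_fast`, `A_slow` (%), `se` (named standard errors), `rss`,
#'   `converged`, `identifiable`.
#' @export
fit_biexponential <- function(curve, n_starts = 5) {
  stopifnot(is.data.frame(curve), all(c("t_h", "percent_nd") %in% names(curve)))
  t <- curve$t_h; y <- curve$percent_nd
  if (length(t) < 5) stop("need at least 5 timepoints")
  if (any(y < -1e-8) || any(y > 100 + 1e-8))
    stop("curve values must lie in [0, 100] percent")
  if (all(abs(y) < 1e-12)) {
    return(structure(list(k_fast = NA_real_, k_slow = NA_real_,
                          A_fast = 0, A_slow = 0,
                          se = c(k_fast = NA, k_slow = NA,
                                 A_fast = NA, A_slow = NA),
                          rss = 0, converged = TRUE, identifiable = FALSE),
                     class = "kinetic_fit"))
  }
  plateau <- max(mean(tail(y, 3)), max(y) * 0.5)
  # early-time slope: y ~ (A_f k_f + A_s k_s) t, dominated by the fast
  # process; seeds the k_fast scale
  early <- which(t > 0)[1]
  slope0 <- y[early] / t[early]
  kf_seed <- max(slope0 / pmax(plateau / 2, 1e-6), 0.05)
  starts <- list(
    c(kf = kf_seed, ks = kf_seed / 40),
    c(kf = kf_seed * 3, ks = kf_seed / 10),
    c(kf = kf_seed / 3, ks = kf_seed / 100),
    c(kf = 1, ks = 0.05),
    c(kf = 5, ks = 0.02))[seq_len(n_starts)]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        percent_nd ~ Af * (1 - exp(-kf * t_h)) + As * (1 - exp(-ks * t_h)),
        data = data.frame(t_h = t, percent_nd = y),
        start = list(kf = s[["kf"]], ks = s[["ks"]],
                     Af = plateau * 0.6, As = plateau * 0.4),
        lower = c(kf = 1e-5, ks = 1e-6, Af = 0, As = 0),
        upper = c(kf = 1e3, ks = 1e2, Af = 100, As = 100),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("biexponential fit failed to converge")
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  if (cf[["Af"]] + cf[["As"]] > 100) {
    # the plateau must stay a percentage: refit with the amplitude-sum
    # bound enforced through a penalty residual
    pen_fn <- function(th) {
      model <- th[["Af"]] * (1 - exp(-th[["kf"]] * t)) +
        th[["As"]] * (1 - exp(-th[["ks"]] * t))
      c(model - y, 1e3 * max(0, th[["Af"]] + th[["As"]] - 100))
    }
    ref <- minpack.lm::nls.lm(
      par = pmin(cf, c(kf = 1e3, ks = 1e2, Af = 60, As = 40)),
      lower = c(kf = 1e-5, ks = 1e-6, Af = 0, As = 0),
      upper = c(kf = 1e3, ks = 1e2, Af = 100, As = 100),
      fn = pen_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- ref$par
    # the penalty leaves sub-0.01 softness at an active bound; project
    if (cf[["Af"]] + cf[["As"]] > 100)
      cf[["As"]] <- max(0, 100 - cf[["Af"]])
    se <- setNames(rep(NA_real_, 4), names(cf))
    best$rss <- sum((pen_fn(cf)[seq_along(y)])^2)
  }
  # label the larger rate fast; tie-break on amplitude
  swap <- cf[["ks"]] > cf[["kf"]] ||
    (cf[["ks"]] == cf[["kf"]] && cf[["As"]] > cf[["Af"]])
  pick <- if (swap) c("ks", "kf", "As", "Af") else c("kf", "ks", "Af", "As")
  out <- structure(list(
    k_fast = cf[[pick[1]]], k_slow = cf[[pick[2]]],
    A_fast = cf[[pick[3]]], A_slow = cf[[pick[4]]],
    se = setNames(as.numeric(se[pick]),
                  c("k_fast", "k_slow", "A_fast", "A_slow")),
    rss = best$rss, converged = TRUE,
    identifiable = TRUE), class = "kinetic_fit")
  if (out$A_fast + out$A_slow > 100 + 1e-6)
    warning("fitted amplitudes exceed 100% (",
            round(out$A_fast + out$A_slow, 2), ")")
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetic_fit> k_fast %.4g 1/h, k_slow %.4g 1/h, A_fast %.3g%%, A_slow %.3g%% (RSS %.4g)\n",
    x$k_fast, x$k_slow, x$A_fast, x$A_slow, x$rss))
  invisible(x)
}

#' Evaluate a biexponential fit
#'
#' @param fit A `kinetic_fit` (or list with the four parameters).
#' @param t Times in hours, >= 0.
#' @return Percent fully deuterated at `t`.
#' @examples
#' tbl <- exchange_parameter_table()
#' dnp3 <- as.list(tbl[tbl$monomer == "BTA-DNP3", ])
#' eval_biexponential(dnp3, 70)  # ~ 79.3, printed as ~80%
#' @export
eval_biexponential <- function(fit, t) {
  biexp_growth(t, fit$k_fast, fit$k_slow, fit$A_fast, fit$A_slow)
}

#' Time-averaged intermediate-species fractions
#'
#' Mean fractions of the (n-1)D and (n-2)D species over an early time
#' window (default the first 2 h) — the solvent-penetration signature:
#' D2O penetrating less ordered parts of the stack exchanges inner
#' hydrogens one at a time, populating these intermediates.
#'
#' @param series A `species_fraction_series`.
#' @param window Two-element window in hours.
#' @return Named numeric: mean fractions of species n-1 and n-2.
#' @export
intermediate_species_summary <- function(series, window = c(0, 2)) {
  stopifnot(inherits(series, "species_fraction_series"),
            length(window) == 2, window[1] < window[2])
  n <- series$monomer$n_labile_total
  if (n < 2) stop("monomer has fewer than 2 labile hydrogens")
  inwin <- series$timepoints >= window[1] & series$timepoints <= window[2]
  if (!any(inwin)) stop("no timepoints fall inside the window")
  setNames(c(mean(series$fractions[inwin, n]),
             mean(series$fractions[inwin, n - 1])),
           paste0("d", c(n - 1, n - 2)))
}

#' Compare kinetic fits across monomers
#'
#' Tabulates the fitted parameters and all pairwise k_fast / k_slow
#' ratios (row i over row j).
#'
#' @param fits Named list of `kinetic_fit` (>= 2).
#' @return List with `parameters` (data.frame) and `ratios`
#'   (data.frame of pairwise rate ratios).
#' @export
compare_monomers <- function(fits) {
  if (!is.list(fits) || length(fits) < 2)
    stop("need at least 2 fits to compare")
  nm <- names(fits)
  if (is.null(nm)) nm <- paste0("fit", seq_along(fits))
  pars <- do.call(rbind, lapply(seq_along(fits), function(i)
    data.frame(monomer = nm[i], k_fast = fits[[i]]$k_fast,
               k_slow = fits[[i]]$k_slow, A_fast = fits[[i]]$A_fast,
               A_slow = fits[[i]]$A_slow)))
  combs <- expand.grid(i = seq_along(fits), j = seq_along(fits))
  combs <- combs[combs$i != combs$j, ]
  ratios <- do.call(rbind, lapply(seq_len(nrow(combs)), function(r) {
    i <- combs$i[r]; j <- combs$j[r]
    data.frame(numerator = nm[i], denominator = nm[j],
               k_fast_ratio = fits[[i]]$k_fast / fits[[j]]$k_fast,
               k_slow_ratio = fits[[i]]$k_slow / fits[[j]]$k_slow)
  }))
  list(parameters = pars, ratios = ratios)
}

#' Write a kinetic fit to JSON
#'
#' @param fit A `kinetic_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kinetic_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
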