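#' Optical constants for SLS reduction
#'
#' Defaults match the goniometer setup used for the BTA samples:
#' toluene reference Rayleigh ratio 2.1e-2 1/m at 532 nm, water solvent
#' (n = 1.333), toluene n = 1.497.
#'
#' @param R_toluene Toluene Rayleigh ratio, 1/m.
#' @param n_solvent,n_toluene Refractive indices.
#' @param wavelength Laser wavelength, nm.
#' @return List of class `optical_constants`.
#' @export
optical_constants <- function(R_toluene = 2.1e-2, n_solvent = 1.333,
                              n_toluene = 1.497, wavelength = 532) {
  stopifnot(R_toluene > 0, n_solvent > 0, n_toluene > 0, wavelength > 0)
  structure(list(R_toluene = R_toluene, n_solvent = n_solvent,
                 n_toluene = n_toluene, wavelength = wavelength),
            class = "optical_constants")
}

#' Excess Rayleigh ratio from count rates
#'
#' R = ((I_sample - I_solvent) / I_toluene) * R_toluene *
#' (n_solvent / n_toluene)^2, the toluene-referenced absolute excess
#' scattering of the solution. A negative excess (sample dimmer than
#' solvent) is reported with a warning, not clipped.
#'
#' @param I_sample,I_solvent,I_toluene Count rates (same units); may be
#'   vectors over angles.
#' @param const [optical_constants()].
#' @return Rayleigh ratio in 1/m.
#' @examples
#' rayleigh_ratio(200, 100, 100)  # one toluene-equivalent excess
#' @export
rayleigh_ratio <- function(I_sample, I_solvent, I_toluene,
                           const = optical_constants()) {
  if (any(I_toluene <= 0)) stop("I_toluene must be > 0")
  if (any(c(I_sample, I_solvent) < 0)) stop("count rates must be >= 0")
  excess <- I_sample - I_solvent
  if (any(excess < 0))
    warning("negative excess scattering (I_sample < I_solvent)")
  (excess / I_toluene) * const$R_toluene *
    (const$n_solvent / const$n_toluene)^2
}

#' Scattering vector magnitude from angle
#'
#' q = 4 pi n sin(theta/2) / lambda, in 1/nm for wavelength in nm.
#'
#' @param angle_deg Scattering angle in degrees, strictly inside
#'   (0, 180).
#' @param const [optical_constants()].
#' @return q in 1/nm.
#' @examples
#' q_from_angle(90)  # ~ 0.0223 1/nm
#' @export
q_from_angle <- function(angle_deg, const = optical_constants()) {
  if (any(angle_deg <= 0 | angle_deg >= 180))
    stop("angle must lie strictly inside (0, 180) degrees")
  4 * pi * const$n_solvent * sin(angle_deg * pi / 360) / const$wavelength
}

#' Reduce an SLS angular scan to R(q)
#'
#' @param scan data.frame with columns `angle_deg`, `I_sample`,
#'   `I_solvent`, `I_toluene`.
#' @param const [optical_constants()].
#' @return data.frame with `q_inv_nm` and `R_inv_m`.
#' @export
reduce_sls <- function(scan, const = optical_constants()) {
  stopifnot(all(c("angle_deg", "I_sample", "I_solvent", "I_toluene")
                %in% names(scan)))
  data.frame(
    q_inv_nm = q_from_angle(scan$angle_deg, const),
    R_inv_m = rayleigh_ratio(scan$I_sample, scan$I_solvent,
                             scan$I_toluene, const))
}

#' Power-law fit of a scattering curve
#'
#' Least-squares slope of log I versus log q over a q window. A slope
#' of -1 is the signature of long rod-like scatterers.
#'
#' @param q,intensity Positive numeric vectors.
#' @param q_window Optional `c(qmin, qmax)` restriction.
#' @return List with `exponent`, `amplitude` (I at q = 1), `se`
#'   (slope standard error), `n`.
#' @export
fit_power_law <- function(q, intensity, q_window = range(q)) {
  keep <- q >= q_window[1] & q <= q_window[2]
  q <- q[keep]; intensity <- intensity[keep]
  if (length(q) < 4) stop("need at least 4 points in the q window")
  if (any(q <= 0) || any(intensity <= 0))
    stop("power-law fit requires positive q and intensity")
  fit <- stats::lm(log(intensity) ~ log(q))
  cf <- coef(fit)
  # summary.lm warns on numerically exact power laws; the se is still 0
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  list(exponent = unname(cf[2]), amplitude = exp(unname(cf[1])),
       se = unname(se), n = length(q))
}

#' Elliptical-cylinder cross-section parameters
#'
#' @param r_minor Minor cross-section radius, Angstrom.
#' @param axis_ratio Long/short semi-axis ratio, >= 1.
#' @param length Cylinder length, Angstrom.
#' @param scale Forward-scattering amplitude (intensity units).
#' @param background Flat background (intensity units).
#' @return List of class `ellipse_cyl_params`.
#' @export
ellipse_cyl_params <- function(r_minor, axis_ratio = 1, length = 5000,
                               scale = 1, background = 0) {
  if (r_minor <= 0 || length <= 0) stop("r_minor and length must be > 0")
  if (axis_ratio < 1) stop("axis_ratio must be >= 1 (long/short)")
  if (scale < 0 || background < 0)
    stop("scale and background must be >= 0")
  structure(list(r_minor = r_minor, axis_ratio = axis_ratio,
                 length = length, scale = scale, background = background),
            class = "ellipse_cyl_params")
}

# Gauss-Legendre nodes/weights on [0, pi/2], cached per order
.gl_cache <- new.env(parent = emptyenv())
.gl_half_pi <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) {
    g <- pracma::gaussLegendre(n, 0, pi / 2)
    .gl_cache[[key]] <- g
  }
  .gl_cache[[key]]
}

# 2 J1(x)/x with the x -> 0 limit; preserves array shape
.j1c <- function(x) {
  out <- x; out[] <- 1
  nz <- abs(x) > 1e-8
  out[nz] <- 2 * besselJ(x[nz], 1) / x[nz]
  out
}

.sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-8
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

#' Orientation-averaged elliptical-cylinder intensity
#'
#' Form factor of a uniform cylinder of length L with elliptical
#' cross-section (semi-axes r_minor and axis_ratio * r_minor), averaged
#' over the cylinder-axis polar angle alpha and the cross-section
#' azimuth phi:
#' F(q, alpha, phi) = sinc(q L cos(alpha) / 2) *
#' 2 J1(q r(phi) sin(alpha)) / (q r(phi) sin(alpha)), with
#' r(phi) = r_minor sqrt(cos^2 phi + axis_ratio^2 sin^2 phi).
#' I(q) = scale * <F^2> + background, normalized so I -> scale +
#' background as q -> 0. Both averages use fixed-order Gauss-Legendre
#' quadrature (deterministic and convergence-tested).
#'
#' @param p An [ellipse_cyl_params()].
#' @param q Scattering vector magnitudes, 1/Angstrom.
#' @param n_alpha,n_phi Quadrature orders.
#' @return Intensity at each `q`.
#' @export
elliptical_cylinder_intensity <- function(p, q, n_alpha = 128, n_phi = 64) {
  stopifnot(inherits(p, "ellipse_cyl_params"))
  if (any(q <= 0)) stop("q must be > 0")
  ga <- .gl_half_pi(n_alpha); gp <- .gl_half_pi(n_phi)
  r_phi <- p$r_minor * sqrt(cos(gp$x)^2 + p$axis_ratio^2 * sin(gp$x)^2)
  sa <- sin(ga$x); ca <- cos(ga$x)
  pf <- vapply(q, function(qi) {
    axial <- .sinc(qi * p$length * ca / 2)
    # cross-section term averaged over phi at each alpha (n_alpha x n_phi)
    cross2 <- (.j1c(outer(qi * sa, r_phi))^2 %*% gp$w) / (pi / 2)
    # solid-angle average over alpha with sin(alpha) weight
    sum(ga$w * axial^2 * as.vector(cross2) * sa)
  }, numeric(1))
  p$scale * pf + p$background
}

#' Orientation-averaged circular-cylinder intensity
#'
#' Independent single-integral implementation (no azimuthal average)
#' used as the degenerate-case oracle for the elliptical model at
#' axis_ratio = 1.
#'
#' @param r Cross-section radius, Angstrom.
#' @param length Cylinder length, Angstrom.
#' @param scale,background Intensity scale and flat background.
#' @param q Scattering vectors, 1/Angstrom.
#' @param n_alpha Quadrature order.
#' @return Intensity at each `q`.
#' @export
circular_cylinder_intensity <- function(r, length, scale, background, q,
                                        n_alpha = 128) {
  if (r <= 0 || length <= 0) stop("r and length must be > 0")
  if (any(q <= 0)) stop("q must be > 0")
  ga <- .gl_half_pi(n_alpha)
  sa <- sin(ga$x); ca <- cos(ga$x)
  pf <- vapply(q, function(qi) {
    f <- .sinc(qi * length * ca / 2) * .j1c(qi * r * sa)
    sum(ga$w * f^2 * sa)
  }, numeric(1))
  scale * pf + background
}

#' Fit the elliptical-cylinder model to a scattering curve
#'
#' Bounded Levenberg-Marquardt least squares on log intensity (the
#' curve spans decades). By default the length is held fixed: when the
#' lowest measured q is well above 1/L the data never reach the Guinier
#' plateau and the length is unidentifiable, so only the cross-section
#' is fitted — the fit flags this regime.
#'
#' @param q,intensity Measured curve (1/Angstrom, intensity units).
#' @param init An [ellipse_cyl_params()] starting point.
#' @param fixed Character vector of parameter names to hold at their
#'   `init` values; default fixes `length` and `background`.
#' @param n_alpha,n_phi Quadrature orders for the forward model.
#' @return List with `params` (fitted [ellipse_cyl_params()]), `rss`
#'   (on log intensity), `se` (standard errors of free parameters),
#'   `length_identifiable`, `converged`.
#' @export
fit_elliptical_cylinder <- function(q, intensity, init,
                                    fixed = c("length", "background"),
                                    n_alpha = 128, n_phi = 64) {
  stopifnot(inherits(init, "ellipse_cyl_params"))
  if (any(intensity <= 0))
    stop("intensities must be > 0 for the log-space fit")
  all_par <- c("r_minor", "axis_ratio", "length", "scale", "background")
  free <- setdiff(all_par, fixed)
  if (length(free) == 0) stop("no free parameters")
  lower <- c(r_minor = 1e-3, axis_ratio = 1, length = 1,
             scale = 1e-12, background = 0)
  upper <- c(r_minor = 1e4, axis_ratio = 50, length = 1e7,
             scale = 1e12, background = 1e6)
  p0 <- unlist(init[all_par])
  resid_fn <- function(theta) {
    p <- p0; p[free] <- theta
    pl <- do.call(ellipse_cyl_params, as.list(p))
    model <- elliptical_cylinder_intensity(pl, q, n_alpha, n_phi)
    log(model) - log(intensity)
  }
  fit <- minpack.lm::nls.lm(
    par = p0[free], lower = lower[free], upper = upper[free],
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  pfit <- p0; pfit[free] <- fit$par
  se <- tryCatch({
    s <- sqrt(diag(vcov(fit)))
    setNames(as.numeric(s), free)
  }, error = function(e) setNames(rep(NA_real_, length(free)), free))
  list(params = do.call(ellipse_cyl_params, as.list(pfit)),
       rss = sum(fit$fvec^2), se = se,
       length_identifiable = min(q) * pfit[["length"]] < 5,
       converged = fit$info %in% 1:4)
}

#' Monomers per fiber cross-section from the axis ratio
#'
#' Rounds the fitted cross-sectional axis ratio to the nearest integer
#' as the monomers-across estimate: an axis ratio of ~2 matches a
#' cross-section of two side-by-side monomers, i.e. a double helix.
#' Documented heuristic, not a structure determination.
#'
#' @param p An [ellipse_cyl_params()] or a bare axis-ratio number.
#' @return Integer monomer count.
#' @examples
#' cross_section_monomer_count(1.87)  # 2
#' @export
cross_section_monomer_count <- function(p) {
  ar <- if (inherits(p, "ellipse_cyl_params")) p$axis_ratio else p
  as.integer(round(ar))
}

#' Simulate a raw SLS angular scan
#'
#' Constructs sample/solvent/toluene count rates whose reduction through
#' [rayleigh_ratio()] reproduces a target excess Rayleigh ratio
#' R(q) = amplitude * q^exponent, with multiplicative Gaussian noise on
#' the sample counts.
#'
#' @param angles Scattering angles in degrees.
#' @param exponent Power-law exponent of the target R(q) (-1 for long
#'   rods).
#' @param amplitude R at q = 1 (in 1/m with q in 1/nm).
#' @param noise_rel Relative noise s.d. on the excess counts.
#' @param const [optical_constants()].
#' @param I_toluene,I_solvent Reference count rates.
#' @param seed Integer seed.
#' @return data.frame with `angle_deg`, `I_sample`, `I_solvent`,
#'   `I_toluene`, plus attribute `truth` (amplitude, exponent).
#' @export
simulate_sls_scan <- function(angles = seq(30, 150, by = 5),
                              exponent = -1, amplitude = 1e-4,
                              noise_rel = 0, const = optical_constants(),
                              I_toluene = 1e5, I_solvent = 2e4,
                              seed = 1L) {
  q <- q_from_angle(angles, const)
  R_target <- amplitude * q^exponent
  excess <- R_target / const$R_toluene /
    (const$n_solvent / const$n_toluene)^2 * I_toluene
  if (noise_rel > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    excess <- excess * (1 + rnorm(length(excess), sd = noise_rel))
  }
  out <- data.frame(angle_deg = angles,
                    I_sample = I_solvent + excess,
                    I_solvent = I_solvent, I_toluene = I_toluene)
  attr(out, "truth") <- list(amplitude = amplitude, exponent = exponent)
  out
}

#' Simulate a SANS curve from the elliptical-cylinder model
#'
#' @param params An [ellipse_cyl_params()] (ground truth).
#' @param q_grid Increasing positive q values, 1/Angstrom.
#' @param noise_rel Relative Gaussian noise s.d.
#' @param seed Integer seed.
#' @param n_alpha,n_phi Quadrature orders.
#' @return data.frame with `q_inv_A`, `I`, `dI`, plus attribute
#'   `truth` = `params`.
#' @export
simulate_sans_curve <- function(params,
                                q_grid = exp(seq(log(3e-3), log(0.4),
                                                 length.out = 60)),
                                noise_rel = 0, seed = 1L,
                                n_alpha = 128, n_phi = 64) {
  stopifnot(inherits(params, "ellipse_cyl_params"))
  if (is.unsorted(q_grid, strictly = TRUE) || any(q_grid <= 0))
    stop("q_grid must be positive and strictly increasing")
  I <- elliptical_cylinder_intensity(params, q_grid, n_alpha, n_phi)
  dI <- noise_rel * I
  if (noise_rel > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    I <- pmax(I * (1 + rnorm(length(I), sd = noise_rel)),
              .Machine$double.xmin)
  }
  out <- data.frame(q_inv_A = q_grid, I = I, dI = dI)
  attr(out, "truth") <- params
  out
}
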