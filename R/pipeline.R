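#' Registered pipeline scenarios
#'
#' @return Character vector of scenario names accepted by
#'   [run_scenario()].
#' @export
pipeline_scenarios <- function() {
  c("mass-calc", "simulate-hdx", "fit-hdx", "sls-reduce", "simulate-sans",
    "fit-sans", "rdf", "extension-map", "tirf-quant", "full-demo")
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML config (or takes a list), fills defaults, and checks
#' invariants. Minimal config: a `scenario` field. Optional fields:
#' `seed` (integer, default 1), `outdir` (default `tempdir()`), and a
#' `params` block passed to the scenario.
#'
#' @param config Path to a YAML file, or a list.
#' @return Object of class `run_config`.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file or a list")
  if (is.null(cfg$scenario))
    stop("config field 'scenario' is required")
  if (!cfg$scenario %in% pipeline_scenarios())
    stop("unknown scenario '", cfg$scenario, "'; valid scenarios: ",
         paste(pipeline_scenarios(), collapse = ", "))
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("config field 'seed' must be an integer")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$outdir)) cfg$outdir <- tempfile("suprafiber-run-")
  if (is.null(cfg$params)) cfg$params <- list()
  if (!is.list(cfg$params)) stop("config field 'params' must be a block")
  for (nm in c("k_fast", "k_slow", "penetration_rate", "noise_rel"))
    if (!is.null(cfg$params[[nm]]) && cfg$params[[nm]] < 0)
      stop("config field 'params.", nm, "' must be >= 0")
  structure(cfg[c("scenario", "seed", "outdir", "params")],
            class = "run_config")
}

# per-module seed fan-out: stable small offsets from the global seed
.derive_seed <- function(seed, stream) {
  offs <- c(hdx = 101L, spectra = 211L, sls = 307L, sans = 401L,
            helix = 503L, tirf = 601L)
  (seed + offs[[stream]]) %% .Machine$integer.max
}

#' Run a pipeline scenario
#'
#' Executes one named scenario end to end — generation and/or analysis —
#' writing its data products under `cfg$outdir` and a `summary.json`
#' capturing inputs, seeds, and package version, enough to regenerate
#' the run.
#'
#' @param cfg A `run_config` from [validate_config()] (or a list
#'   accepted by it).
#' @return The summary list, invisibly; its `outputs` entry names the
#'   files written.
#' @export
run_scenario <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  summary <- list(scenario = cfg$scenario, seed = cfg$seed,
                  params = p,
                  package_version =
                    as.character(utils::packageVersion("suprafiber")))
  out <- switch(cfg$scenario,
    "mass-calc" = .scn_mass_calc(p),
    "simulate-hdx" = .scn_simulate_hdx(cfg, p),
    "fit-hdx" = .scn_fit_hdx(cfg, p),
    "sls-reduce" = .scn_sls(cfg, p),
    "simulate-sans" = .scn_simulate_sans(cfg, p),
    "fit-sans" = .scn_fit_sans(cfg, p),
    "rdf" = .scn_rdf(cfg, p),
    "extension-map" = .scn_extension_map(cfg, p),
    "tirf-quant" = .scn_tirf(cfg, p),
    "full-demo" = .scn_full_demo(cfg, p))
  summary <- c(summary, out)
  path <- file.path(cfg$outdir, "summary.json")
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  summary$outputs <- c(out$outputs, "summary.json")
  invisible(summary)
}

.get <- function(p, name, default) if (is.null(p[[name]])) default else p[[name]]

.scn_mass_calc <- function(p) {
  formulas <- .get(p, "formulas",
                   c("C120H201N15O42", "C86H153N7O26"))
  rows <- lapply(formulas, function(fs) {
    f <- parse_formula(fs)
    list(formula = fs,
         average_mass_gmol = round(average_mass(f), 2),
         monoisotopic_mass_da = round(monoisotopic_mass(f), 2),
         mz_z1_proton = round(mz_for_charge(monoisotopic_mass(f), 1), 4))
  })
  list(results = rows, outputs = character(0))
}

.scn_simulate_hdx <- function(cfg, p) {
  mono <- study_monomer(.get(p, "monomer", "BTA-DNP3"))
  tbl <- exchange_parameter_table()
  row <- tbl[tbl$monomer == mono$name, ]
  if (nrow(row) == 0) row <- tbl[1, ]
  sim <- exchange_sim_config(
    mono, k_fast = .get(p, "k_fast", row$k_fast),
    k_slow = .get(p, "k_slow", row$k_slow),
    A_fast = .get(p, "A_fast", row$A_fast),
    A_slow = .get(p, "A_slow", row$A_slow),
    penetration_rate = .get(p, "penetration_rate", 0),
    noise_rel = .get(p, "noise_rel", 0.02),
    seed = .derive_seed(cfg$seed, "hdx"))
  series <- simulate_species_fractions(sim)
  pattern <- isotope_pattern(mono$formula)
  spectra <- spectra_from_fractions(series, pattern,
                                    noise_rel = sim$noise_rel,
                                    seed = .derive_seed(cfg$seed,
                                                        "spectra"))
  f_spec <- file.path(cfg$outdir, "hdx_spectra.csv")
  write_hdx_spectra(spectra, f_spec)
  f_truth <- file.path(cfg$outdir, "hdx_truth.json")
  jsonlite::write_json(
    list(monomer = mono$name, timepoints_h = series$timepoints,
         fractions = unname(apply(series$fractions, 1, as.list))),
    f_truth, auto_unbox = TRUE, digits = NA)
  list(monomer = mono$name,
       outputs = basename(c(f_spec, f_truth)))
}

.scn_fit_hdx <- function(cfg, p) {
  mono <- study_monomer(.get(p, "monomer", "BTA-DNP3"))
  spectra_path <- .get(p, "spectra", file.path(cfg$outdir,
                                               "hdx_spectra.csv"))
  ss <- read_hdx_spectra(spectra_path, monomer = mono)
  pattern <- isotope_pattern(mono$formula)
  series <- deconvolve_series(ss, pattern, mono)
  curve <- fully_deuterated_curve(series)
  fit <- fit_biexponential(curve)
  f_curve <- file.path(cfg$outdir, "fully_deuterated_curve.csv")
  utils::write.csv(curve, f_curve, row.names = FALSE)
  f_fit <- file.path(cfg$outdir, "kinetic_fit.json")
  write_kinetic_fit(fit, f_fit)
  list(fit = unclass(fit)[c("k_fast", "k_slow", "A_fast", "A_slow",
                            "rss")],
       outputs = basename(c(f_curve, f_fit)))
}

.scn_sls <- function(cfg, p) {
  scan <- simulate_sls_scan(
    exponent = .get(p, "exponent", -1),
    amplitude = .get(p, "amplitude", 1e-4),
    noise_rel = .get(p, "noise_rel", 0),
    seed = .derive_seed(cfg$seed, "sls"))
  red <- reduce_sls(scan)
  pl <- fit_power_law(red$q_inv_nm, red$R_inv_m)
  f <- file.path(cfg$outdir, "sls_reduced.csv")
  utils::write.csv(red, f, row.names = FALSE)
  list(power_law = pl[c("exponent", "amplitude")],
       outputs = basename(f))
}

.scn_sans_truth <- function(p) {
  ellipse_cyl_params(
    r_minor = .get(p, "r_minor", 15),
    axis_ratio = .get(p, "axis_ratio", 1.87),
    length = .get(p, "length", 5000),
    scale = .get(p, "scale", 1),
    background = .get(p, "background", 0))
}

.scn_simulate_sans <- function(cfg, p) {
  truth <- .scn_sans_truth(p)
  curve <- simulate_sans_curve(truth,
                               noise_rel = .get(p, "noise_rel", 0),
                               seed = .derive_seed(cfg$seed, "sans"))
  f <- file.path(cfg$outdir, "sans_curve.csv")
  utils::write.csv(curve, f, row.names = FALSE)
  f_t <- file.path(cfg$outdir, "sans_truth.json")
  jsonlite::write_json(unclass(truth), f_t, auto_unbox = TRUE,
                       digits = NA)
  list(truth = unclass(truth), outputs = basename(c(f, f_t)))
}

.scn_fit_sans <- function(cfg, p) {
  path <- .get(p, "curve", file.path(cfg$outdir, "sans_curve.csv"))
  d <- utils::read.csv(path)
  init <- ellipse_cyl_params(
    r_minor = .get(p, "init_r_minor", 12),
    axis_ratio = .get(p, "init_axis_ratio", 1.3),
    length = .get(p, "length", 5000),
    scale = .get(p, "init_scale", max(d$I)),
    background = 0)
  fit <- fit_elliptical_cylinder(d$q_inv_A, d$I, init)
  f <- file.path(cfg$outdir, "sans_fit.json")
  jsonlite::write_json(
    list(params = unclass(fit$params), rss = fit$rss,
         monomers_per_cross_section =
           cross_section_monomer_count(fit$params)),
    f, auto_unbox = TRUE, digits = NA)
  list(fit = unclass(fit$params),
       monomers_per_cross_section =
         cross_section_monomer_count(fit$params),
       outputs = basename(f))
}

.scn_helix <- function(cfg, p) {
  build_double_helix_trajectory(
    helix_config(
      monomers_per_helix = .get(p, "monomers_per_helix", 9),
      rise = .get(p, "rise", 3.4),
      jitter_sd = .get(p, "jitter_sd", 0),
      folded_fraction = .get(p, "folded_fraction", 0),
      n_frames = .get(p, "n_frames", 10),
      seed = .derive_seed(cfg$seed, "helix")))
}

.scn_rdf <- function(cfg, p) {
  traj <- .scn_helix(cfg, p)
  prof <- core_rdf(traj, helix = .get(p, "helix", "h1"),
                   bin_width = .get(p, "bin_width", 0.1),
                   r_max = .get(p, "r_max", 12))
  f <- file.path(cfg$outdir, "rdf.csv")
  utils::write.csv(as.data.frame(prof), f, row.names = FALSE)
  sc <- stacking_order_score(prof, rise = .get(p, "rise", 3.4))
  list(peaks = peak_positions(prof), stacking_score = sc$score,
       outputs = basename(f))
}

.scn_extension_map <- function(cfg, p) {
  traj <- .scn_helix(cfg, p)
  map <- side_chain_extension_map(traj)
  f <- file.path(cfg$outdir, "extension_map.csv")
  utils::write.csv(as.data.frame(map), f, row.names = FALSE)
  list(n_folded = sum(map$class == "folded"),
       n_extended = sum(map$class == "extended"),
       outputs = basename(f))
}

.scn_tirf <- function(cfg, p) {
  sim <- image_sim_config(
    size = .get(p, "size", 96),
    green_on_fiber = .get(p, "green_on_fiber", 80),
    poisson_scale = .get(p, "poisson_scale", 0),
    gauss_sd = .get(p, "gauss_sd", 0),
    n_timepoints = .get(p, "n_timepoints", 8),
    fiber_paths = default_fiber_paths(.get(p, "size", 96)),
    seed = .derive_seed(cfg$seed, "tirf"))
  rate <- .get(p, "binding_rate", 1)
  stack <- render_fiber_image_series(sim, function(t) 1 - exp(-rate * t))
  bt <- binding_time_course(stack)
  f <- file.path(cfg$outdir, "binding_course.csv")
  utils::write.csv(bt$course, f, row.names = FALSE)
  list(plateau = bt$plateau, saturation_time = bt$saturation_time,
       outputs = basename(f))
}

.scn_full_demo <- function(cfg, p) {
  # end-to-end: mass arithmetic, exchange-kinetics round trip on the
  # fitted copolymer parameters, SANS round trip, stacking metrics
  masses <- .scn_mass_calc(list())
  hdx <- .scn_simulate_hdx(cfg, p)
  fit <- .scn_fit_hdx(cfg, c(p, list(monomer = hdx$monomer)))
  sans_sim <- .scn_simulate_sans(cfg, p)
  sans_fit <- .scn_fit_sans(cfg, p)
  rdf <- .scn_rdf(cfg, p)
  list(masses = masses$results, hdx_fit = fit$fit,
       sans_fit = sans_fit$fit,
       monomers_per_cross_section = sans_fit$monomers_per_cross_section,
       rdf_peaks = rdf$peaks,
       outputs = c(hdx$outputs, fit$outputs, sans_sim$outputs,
                   sans_fit$outputs, rdf$outputs))
}
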