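#' Element mass and natural-abundance table
#'
#' Static table of standard atomic weights and natural isotope
#' compositions (IUPAC/CIAAW 2021 values, conventional weights for
#' elements quoted as intervals). Covers the elements occurring in the
#' BTA monomer formulas plus common adduct/hetero atoms.
#'
#' Each entry carries the standard atomic weight in g/mol and a matrix
#' of (isotope mass in Da, natural abundance) rows, masses strictly
#' increasing, abundances summing to 1 within 1e-6.
#'
#' @return A list with components `elements` (named list described
#'   above), `proton_mass` (Da), and `dh_mass_diff` (mass difference
#'   between deuterium and protium, Da).
#' @examples
#' mt <- mass_table()
#' mt$elements$C$weight
#' @export
mass_table <- function() {
  iso <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    colnames(m) <- c("mass", "abundance")
    m
  }
  elements <- list(
    H = list(weight = 1.008, isotopes = iso(
      1.00782503207, 0.999885,
      2.01410177812, 0.000115)),
    C = list(weight = 12.011, isotopes = iso(
      12.0000000, 0.9893,
      13.00335483507, 0.0107)),
    N = list(weight = 14.007, isotopes = iso(
      14.00307400443, 0.996205,
      15.00010889888, 0.003795)),
    O = list(weight = 15.999, isotopes = iso(
      15.99491461957, 0.99757,
      16.99913175650, 0.00038,
      17.99915961286, 0.00205)),
    S = list(weight = 32.06, isotopes = iso(
      31.97207117440, 0.9499,
      32.97145890980, 0.0075,
      33.96786700400, 0.0425,
      35.96708070600, 0.0001)),
    P = list(weight = 30.973761998, isotopes = iso(
      30.97376199842, 1.0)),
    B = list(weight = 10.81, isotopes = iso(
      10.01293695, 0.199,
      11.00930536, 0.801)),
    Na = list(weight = 22.98976928, isotopes = iso(
      22.98976928196, 1.0)),
    K = list(weight = 39.0983, isotopes = iso(
      38.96370648640, 0.932581,
      39.96399816600, 0.000117,
      40.96182525790, 0.067302)),
    Cl = list(weight = 35.45, isotopes = iso(
      34.96885268200, 0.7576,
      36.96590260200, 0.2424)),
    F = list(weight = 18.998403163, isotopes = iso(
      18.99840316273, 1.0))
  )
  list(
    elements = elements,
    proton_mass = 1.007276466621,
    # 2H minus 1H: the envelope shift per exchanged labile hydrogen
    dh_mass_diff = 2.01410177812 - 1.00782503207
  )
}

.mass_table_check <- function(mt) {
  for (el in names(mt$elements)) {
    e <- mt$elements[[el]]
    stopifnot(abs(sum(e$isotopes[, "abundance"]) - 1) < 1e-6)
    stopifnot(all(diff(e$isotopes[, "mass"]) > 0))
  }
  invisible(TRUE)
}
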