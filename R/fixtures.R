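#' Study monomer specifications
#'
#' The water-soluble BTA monomers of the copolymer study. BTA-DNP1 and
#' BTA-DNP3 carry their reported molecular formulas; BTA-(OH)3 and
#' BTA-Ba use nominal formulas of the right composition class (their
#' exact formulas are not needed by any analysis — only the labile
#' hydrogen bookkeeping and mole fractions are).
#'
#' Labile hydrogens: BTA-(OH)3 has six (three outer hydroxyl + three
#' inner core-amide NH); BTA-DNP3 has nine (three outer linker-amide
#' NH + three outer DNP aryl NH + three inner core-amide NH). The
#' outer groups exchange immediately upon dilution into D2O; the inner
#' amides are shielded within the hydrophobic stack.
#'
#' @param which One of `"BTA-(OH)3"`, `"BTA-DNP1"`, `"BTA-DNP3"`,
#'   `"BTA-Ba"`.
#' @return A [monomer_spec()].
#' @examples
#' study_monomer("BTA-DNP3")
#' @export
study_monomer <- function(which = c("BTA-(OH)3", "BTA-DNP1", "BTA-DNP3",
                                    "BTA-Ba")) {
  which <- match.arg(which)
  switch(which,
    "BTA-(OH)3" = monomer_spec("BTA-(OH)3", "C66H123N3O15",
                               n_outer = 3, n_inner = 3,
                               mole_fraction = 0.965),
    "BTA-DNP1" = monomer_spec("BTA-DNP1", "C86H153N7O26",
                              n_outer = 4, n_inner = 3,
                              mole_fraction = 0.075),
    "BTA-DNP3" = monomer_spec("BTA-DNP3", "C120H201N15O42",
                              n_outer = 6, n_inner = 3,
                              mole_fraction = 0.025),
    "BTA-Ba" = monomer_spec("BTA-Ba", "C73H130BN5O17",
                            n_outer = 4, n_inner = 3,
                            mole_fraction = 0.01))
}

#' Fitted exchange-kinetics parameters of the copolymer monomers
#'
#' Rate constants (1/h) and amplitude contributions (%) of the fast and
#' slow hydrogen/deuterium exchange processes obtained for BTA-(OH)3 and
#' BTA-DNP3 within the BTA-DNP3:BTA-Ba:BTA-(OH)3 (2.5:1:96.5) copolymer.
#' These parameter rows drive the synthetic-curve fixtures for
#' parameter-recovery studies.
#'
#' @return data.frame with columns `monomer`, `k_fast`, `k_slow`
#'   (1/h), `A_fast`, `A_slow` (percent).
#' @examples
#' exchange_parameter_table()
#' @export
exchange_parameter_table <- function() {
  data.frame(
    monomer = c("BTA-(OH)3", "BTA-DNP3"),
    k_fast = c(3.45, 0.76),
    k_slow = c(0.08, 0.05),
    A_fast = c(35.5, 65.5),
    A_slow = c(28.6, 14.2),
    stringsAsFactors = FALSE)
}

#' Default HDX sampling timepoints
#'
#' Dilution experiments are sampled densely at early times (fast
#' process, half-life under an hour) and sparsely out to 70 h (slow
#' process): t = 0 plus `n - 1` log-spaced points between `t_min` and
#' `t_max` hours.
#'
#' @param n Total number of timepoints (including t = 0).
#' @param t_min First nonzero timepoint (h).
#' @param t_max Last timepoint (h).
#' @return Increasing numeric vector of times in hours.
#' @export
default_hdx_timepoints <- function(n = 15, t_min = 0.25, t_max = 70) {
  c(0, 10^seq(log10(t_min), log10(t_max), length.out = n - 1))
}
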