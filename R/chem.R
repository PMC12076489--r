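#' Parse a molecular formula string
#'
#' Parses Hill-style element-count tokens ("C120H201N15O42") into a
#' named count vector. Counts default to 1 when omitted ("H2O" has O:1).
#'
#' @param text Formula string, element symbols each optionally followed
#'   by a positive integer count.
#' @return Object of class `molecular_formula`: a named integer vector
#'   of element counts, in first-appearance order.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C120H201N15O42")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  txt <- gsub("\\s", "", text)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", txt)[[1]]
  tokens <- regmatches(txt, gregexpr("([A-Z][a-z]?)([0-9]*)", txt))[[1]]
  if (sum(nchar(tokens)) != nchar(txt))
    stop("unparseable characters in formula: ", text)
  known <- names(mass_table()$elements)
  counts <- integer(0)
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!(sym %in% known))
      stop("unknown element symbol: ", sym)
    if (n <= 0L)
      stop("zero or negative count for element ", sym)
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  structure(counts, class = "molecular_formula")
}

#' Write a formula back to its canonical string
#'
#' Hill convention: C first, then H, then other elements alphabetically.
#' `parse_formula(format_formula(f))` returns counts equal to `f`.
#'
#' @param f A `molecular_formula` or named count vector.
#' @return Single formula string.
#' @export
format_formula <- function(f) {
  f <- .as_formula(f)
  syms <- names(f)
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(vapply(ord, function(s)
    paste0(s, if (f[[s]] > 1L) f[[s]] else ""), character(1)), collapse = "")
}

.as_formula <- function(f) {
  if (inherits(f, "molecular_formula")) return(f)
  if (is.null(f) || length(f) == 0L)
    return(structure(integer(0), class = "molecular_formula"))
  if (is.character(f) && length(f) == 1L) return(parse_formula(f))
  stopifnot(!is.null(names(f)), all(f >= 1))
  structure(setNames(as.integer(f), names(f)), class = "molecular_formula")
}

.element_entry <- function(sym, mt) {
  e <- mt$elements[[sym]]
  if (is.null(e)) stop("element missing from mass table: ", sym)
  e
}

#' Average molecular mass
#'
#' Sum of count times standard atomic weight. For display, round to two
#' decimals (the convention used for calculated MW of the BTA monomers,
#' e.g. 2525.99 g/mol for C120H201N15O42).
#'
#' @param f Formula (string, named counts, or `molecular_formula`).
#' @param mt Mass table, defaults to [mass_table()].
#' @return Average mass in g/mol (full precision).
#' @examples
#' average_mass("C120H201N15O42")  # 2525.99
#' @export
average_mass <- function(f, mt = mass_table()) {
  f <- .as_formula(f)
  if (length(f) == 0L) return(0)
  sum(vapply(names(f), function(s)
    f[[s]] * .element_entry(s, mt)$weight, numeric(1)))
}

#' Monoisotopic mass
#'
#' Sum of count times the mass of each element's most abundant isotope
#' (for C/H/N/O these are also the lightest).
#'
#' @inheritParams average_mass
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C86H153N7O26")  # rounds to 1700
#' @export
monoisotopic_mass <- function(f, mt = mass_table()) {
  f <- .as_formula(f)
  if (length(f) == 0L) return(0)
  sum(vapply(names(f), function(s) {
    iso <- .element_entry(s, mt)$isotopes
    f[[s]] * iso[which.max(iso[, "abundance"]), "mass"]
  }, numeric(1)))
}

#' m/z for a charge state
#'
#' Protonated species: (M + z * m_proton) / z. Sodiated species are
#' supported for z = 1 only ([M+Na]+).
#'
#' @param neutral_mass Neutral mass in Da.
#' @param z Positive integer charge.
#' @param adduct `"proton"` or `"sodium"`.
#' @param mt Mass table.
#' @return m/z value.
#' @export
mz_for_charge <- function(neutral_mass, z, adduct = c("proton", "sodium"),
                          mt = mass_table()) {
  adduct <- match.arg(adduct)
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z))
    stop("z must be a positive integer")
  if (adduct == "proton")
    return((neutral_mass + z * mt$proton_mass) / z)
  if (z != 1L)
    stop("sodium adduct supported for z = 1 only")
  # Na+ = atomic Na minus one electron mass
  neutral_mass + (22.98976928196 - 0.000548579909)
}

#' Natural isotopologue pattern of a formula
#'
#' Builds the isotopologue mass/abundance distribution by iterative
#' per-element convolution of single-atom distributions, pruning peaks
#' below `abundance_cutoff` after each element and renormalizing once at
#' the end (bounded memory on large formulas). Peaks within 1e-9 Da are
#' merged.
#'
#' @param f Formula.
#' @param abundance_cutoff Relative-abundance truncation threshold,
#'   in \[0, 0.01\].
#' @param mt Mass table.
#' @param order `"mass"` (default) or `"abundance"` peak ordering.
#' @return Object of class `isotope_pattern`: data.frame with columns
#'   `mass` (Da) and `abundance` (summing to 1).
#' @examples
#' isotope_pattern("C1")  # ~ 0.989 / 0.011 doublet
#' @export
isotope_pattern <- function(f, abundance_cutoff = 1e-6, mt = mass_table(),
                            order = c("mass", "abundance")) {
  order <- match.arg(order)
  if (!is.numeric(abundance_cutoff) || abundance_cutoff < 0 ||
      abundance_cutoff > 0.01)
    stop("abundance_cutoff must lie in [0, 0.01]")
  f <- .as_formula(f)
  peaks <- data.frame(mass = 0, abundance = 1)
  for (sym in names(f)) {
    iso <- .element_entry(sym, mt)$isotopes
    atom <- data.frame(mass = iso[, "mass"], abundance = iso[, "abundance"])
    for (i in seq_len(f[[sym]])) {
      peaks <- .convolve_patterns(peaks, atom)
      keep <- peaks$abundance >= abundance_cutoff * max(peaks$abundance)
      peaks <- peaks[keep, , drop = FALSE]
    }
  }
  peaks$abundance <- peaks$abundance / sum(peaks$abundance)
  peaks <- peaks[order(if (order == "mass") peaks$mass else -peaks$abundance), ]
  rownames(peaks) <- NULL
  structure(peaks, class = c("isotope_pattern", "data.frame"))
}

.convolve_patterns <- function(a, b) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$abundance, b$abundance)
  d <- data.frame(mass = as.vector(mass), abundance = as.vector(ab))
  # merge numerically identical isotopologue masses
  key <- round(d$mass / 1e-9)
  agg <- rowsum(d$abundance, key)
  m <- rowsum(d$mass * d$abundance, key) / agg
  data.frame(mass = as.vector(m), abundance = as.vector(agg))
}

#' Export an isotope pattern as two-column CSV
#'
#' @param pattern An `isotope_pattern`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_isotope_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "isotope_pattern"))
  utils::write.csv(
    data.frame(mass_da = pattern$mass, abundance = pattern$abundance),
    path, row.names = FALSE)
  invisible(path)
}

#' Construct and validate a monomer specification
#'
#' A monomer spec records the molecular formula, the number of labile
#' (exchangeable) hydrogens split into outer (hydroxyl / outer amide,
#' exchanging immediately upon dilution into D2O) and inner (amide NH
#' shielded inside the hydrophobic stack), and the monomer's mole
#' fraction in the copolymer. The outer/inner partition is input
#' metadata: the labile counts of the BTA monomers are known (six for
#' BTA-(OH)3, nine for BTA-DNP3) but no structure-perception rule is
#' applied.
#'
#' @param name Monomer name.
#' @param formula Formula string or `molecular_formula`.
#' @param n_outer Number of instantly exchanging outer OH/NH hydrogens.
#' @param n_inner Number of shielded inner amide NH hydrogens.
#' @param n_labile_total Total labile hydrogens; defaults to
#'   `n_outer + n_inner`.
#' @param mole_fraction Mole fraction of this monomer in the copolymer.
#' @return Object of class `monomer_spec`.
#' @examples
#' monomer_spec("BTA-(OH)3", "C66H123N3O15", n_outer = 3, n_inner = 3)
#' @export
monomer_spec <- function(name, formula, n_outer, n_inner,
                         n_labile_total = n_outer + n_inner,
                         mole_fraction = 1) {
  s <- structure(list(
    name = name, formula = .as_formula(formula),
    n_labile_total = as.integer(n_labile_total),
    n_outer = as.integer(n_outer), n_inner = as.integer(n_inner),
    mole_fraction = mole_fraction), class = "monomer_spec")
  validate_monomer_spec(s)
}

#' Validate a monomer specification
#'
#' Enforces the spec invariants: outer + inner = total labile count, the
#' labile count does not exceed the formula's hydrogen count, and the
#' mole fraction lies in \[0, 1\].
#'
#' @param s A `monomer_spec`.
#' @return `s`, unchanged, if valid; otherwise an error.
#' @export
validate_monomer_spec <- function(s) {
  stopifnot(inherits(s, "monomer_spec"))
  if (s$n_outer < 0L || s$n_inner < 0L)
    stop("labile hydrogen counts must be non-negative")
  if (s$n_outer + s$n_inner != s$n_labile_total)
    stop("n_outer + n_inner must equal n_labile_total (",
         s$n_outer, " + ", s$n_inner, " != ", s$n_labile_total, ")")
  n_h <- if ("H" %in% names(s$formula)) s$formula[["H"]] else 0L
  if (s$n_labile_total > n_h)
    stop("labile hydrogen count (", s$n_labile_total,
         ") exceeds formula hydrogens (", n_h, ")")
  if (s$mole_fraction < 0 || s$mole_fraction > 1)
    stop("mole_fraction must lie in [0, 1]")
  s
}

#' @export
print.monomer_spec <- function(x, ...) {
  cat(sprintf("<monomer_spec> %s  %s  MW %.2f g/mol\n", x$name,
              format_formula(x$formula), average_mass(x$formula)))
  cat(sprintf("  labile H: %d (outer %d, inner %d), mole fraction %.4g\n",
              x$n_labile_total, x$n_outer, x$n_inner, x$mole_fraction))
  invisible(x)
}

#' Read monomer specs from a key-value config block
#'
#' YAML config: a list of blocks each with fields `name`, `formula`,
#' `n_outer`, `n_inner`, optional `mole_fraction`.
#'
#' @param path YAML file path.
#' @return List of `monomer_spec`.
#' @export
read_monomer_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(b) {
    monomer_spec(b$name, b$formula, b$n_outer, b$n_inner,
                 mole_fraction = if (is.null(b$mole_fraction)) 1
                                 else b$mole_fraction)
  })
}
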