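#' Configuration for the double-helix trajectory generator
#'
#' Emulates the geometry of a BTA double fiber: two interleaved helical
#' strands of stacked monomer cores (rise along the fiber axis, twist
#' per step, strand two offset axially), each monomer carrying labeled
#' side-chain endpoints placed at a folded or extended distance from
#' its core.
#'
#' @param monomers_per_helix Monomers per strand (study value 9).
#' @param n_helices Number of strands; the double-helix morphology of
#'   this system fixes it at 2.
#' @param rise Axial spacing between stacked cores, Angstrom
#'   (characteristic BTA value 3.4). Cores of a strand stack directly
#'   on top of one another along the strand axis, so the intra-strand
#'   nearest-neighbor distance equals the rise exactly.
#' @param twist Azimuthal rotation of the side-chain arms per stacking
#'   step, degrees (the cores themselves stay on the strand axis).
#' @param helix_offset Axial offset of the second strand, Angstrom.
#' @param core_radius Radial distance of cores from the fiber axis.
#' @param jitter_sd Per-frame isotropic Gaussian positional jitter s.d.
#' @param folded_fraction Fraction of monomers whose side chains are
#'   back-folded.
#' @param n_frames Number of trajectory frames.
#' @param seed Integer seed (fold assignment and jitter).
#' @return List of class `helix_config`.
#' @export
helix_config <- function(monomers_per_helix = 9, n_helices = 2,
                         rise = 3.4, twist = 60, helix_offset = 1.7,
                         core_radius = 2, jitter_sd = 0,
                         folded_fraction = 0, n_frames = 10, seed = 1L) {
  if (monomers_per_helix < 1) stop("monomers_per_helix must be >= 1")
  if (n_helices != 2) stop("this study's morphology is a double helix")
  if (rise <= 0) stop("rise must be > 0")
  if (folded_fraction < 0 || folded_fraction > 1)
    stop("folded_fraction must lie in [0, 1]")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(list(monomers_per_helix = monomers_per_helix,
                 n_helices = n_helices, rise = rise, twist = twist,
                 helix_offset = helix_offset, core_radius = core_radius,
                 jitter_sd = jitter_sd, folded_fraction = folded_fraction,
                 n_frames = n_frames, seed = as.integer(seed)),
            class = "helix_config")
}

#' Side-chain placement specification
#'
#' Endpoint labels and their folded/extended core-to-endpoint
#' distances. Defaults follow the back-folding diagnostic: extended
#' side chains sit > 25 Angstrom from the core, folded ones < 20.
#' Labels are kept to four characters so they survive the PDB atom-name
#' field.
#'
#' @param labels Side-chain endpoint labels: `OH` (hydroxyl terminus),
#'   `NHL` (amide NH at the linker start), `NHD` (terminal NH, e.g. of
#'   the DNP motif).
#' @param folded_distance,extended_distance Core-to-endpoint distances
#'   (Angstrom) for folded and extended ground truth.
#' @return List of class `side_chain_spec`.
#' @export
side_chain_spec <- function(labels = c("OH", "NHL", "NHD"),
                            folded_distance = 15, extended_distance = 28) {
  stopifnot(length(labels) >= 1, folded_distance < extended_distance)
  structure(list(labels = labels, folded_distance = folded_distance,
                 extended_distance = extended_distance),
            class = "side_chain_spec")
}

#' Build a synthetic double-helix trajectory
#'
#' Core centroids stack along two parallel strand axes (strand s at
#' azimuth s * 180 degrees, radius core_radius from the fiber axis,
#' axially shifted by s * helix_offset), one core every `rise`
#' Angstrom, so the intra-strand nearest-neighbor core distance equals
#' the rise exactly. The side-chain arms of monomer i are rotated by
#' i * twist and point outward at the folded or extended distance
#' according to the per-monomer ground-truth fold state (drawn once
#' with probability `folded_fraction`). Each frame adds independent
#' isotropic Gaussian jitter to every point.
#'
#' @param cfg A [helix_config()].
#' @param chains A [side_chain_spec()].
#' @return Object of class `fiber_trajectory`: list with `frames`
#'   (each a data.frame helix, index, label, x, y, z), `truth`
#'   (data.frame helix, index, fold with levels folded/extended), and
#'   `config`.
#' @export
build_double_helix_trajectory <- function(cfg = helix_config(),
                                          chains = side_chain_spec()) {
  stopifnot(inherits(cfg, "helix_config"),
            inherits(chains, "side_chain_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  helices <- paste0("h", seq_len(cfg$n_helices))
  mono <- expand.grid(index = seq_len(cfg$monomers_per_helix),
                      helix = helices, stringsAsFactors = FALSE)
  folded <- runif(nrow(mono)) < cfg$folded_fraction
  truth <- data.frame(helix = mono$helix, index = mono$index,
                      fold = ifelse(folded, "folded", "extended"),
                      stringsAsFactors = FALSE)
  base <- do.call(rbind, lapply(seq_len(nrow(mono)), function(m) {
    s <- match(mono$helix[m], helices) - 1L
    i <- mono$index[m] - 1L
    phase <- s * pi
    core <- c(cfg$core_radius * cos(phase), cfg$core_radius * sin(phase),
              i * cfg$rise + s * cfg$helix_offset)
    d <- if (folded[m]) chains$folded_distance else chains$extended_distance
    rows <- data.frame(helix = mono$helix[m], index = mono$index[m],
                       label = "core", x = core[1], y = core[2],
                       z = core[3], stringsAsFactors = FALSE)
    for (k in seq_along(chains$labels)) {
      # arms spread azimuthally and rotated by the per-step twist
      arm <- phase + i * cfg$twist * pi / 180 +
        (k - (length(chains$labels) + 1) / 2) * 0.35
      ep <- core + d * c(cos(arm), sin(arm), 0)
      rows <- rbind(rows, data.frame(
        helix = mono$helix[m], index = mono$index[m],
        label = chains$labels[k], x = ep[1], y = ep[2], z = ep[3],
        stringsAsFactors = FALSE))
    }
    rows
  }))
  frames <- lapply(seq_len(cfg$n_frames), function(f) {
    fr <- base
    if (cfg$jitter_sd > 0) {
      n <- nrow(fr)
      fr$x <- fr$x + rnorm(n, sd = cfg$jitter_sd)
      fr$y <- fr$y + rnorm(n, sd = cfg$jitter_sd)
      fr$z <- fr$z + rnorm(n, sd = cfg$jitter_sd)
    }
    fr
  })
  structure(list(frames = frames, truth = truth, config = cfg),
            class = "fiber_trajectory")
}

.traj_check <- function(traj) {
  stopifnot(inherits(traj, "fiber_trajectory"), length(traj$frames) >= 1)
  n0 <- nrow(traj$frames[[1]])
  for (fr in traj$frames)
    if (nrow(fr) != n0) stop("inconsistent point count across frames")
  invisible(TRUE)
}

#' Intra-helix core radial distribution function
#'
#' Histogram of all core-core pair distances within one helix, pooled
#' over frames, on uniform bins centered at multiples of `bin_width`
#' (so an ideal-lattice distance falls at a bin center, not an edge).
#' Normalized so that a structureless reference with pair distances
#' uniform on \[0, r_max\] gives g(r) = 1: g = counts /
#' (N_pairs_in_range * bin_width / r_max). Inter-helix pairs are
#' excluded — the per-helix curves are the stacking-order readout.
#'
#' @param traj A `fiber_trajectory`.
#' @param helix Helix id, e.g. `"h1"`.
#' @param bin_width Bin width, Angstrom.
#' @param r_max Histogram range, Angstrom.
#' @return Object of class `rdf_profile`: data.frame `r` (bin centers),
#'   `g`, with attributes `bin_width`, `r_max`, `n_frames`.
#' @export
core_rdf <- function(traj, helix = "h1", bin_width = 0.1, r_max = 12) {
  .traj_check(traj)
  if (bin_width <= 0 || r_max < bin_width)
    stop("need bin_width > 0 and r_max >= bin_width")
  dists <- unlist(lapply(traj$frames, function(fr) {
    cores <- fr[fr$label == "core" & fr$helix == helix, c("x", "y", "z")]
    if (nrow(cores) < 2)
      stop("need >= 2 core points in helix ", helix)
    as.vector(stats::dist(cores))
  }))
  dists <- dists[dists <= r_max]
  breaks <- seq(bin_width / 2, by = bin_width,
                length.out = ceiling(r_max / bin_width) + 1)
  centers <- breaks[-length(breaks)] + bin_width / 2
  counts <- hist(dists[dists > breaks[1] & dists <= max(breaks)],
                 breaks = breaks, plot = FALSE)$counts
  g <- if (length(dists) > 0)
    counts / (length(dists) * bin_width / r_max) else counts * 0
  structure(data.frame(r = centers, g = g),
            class = c("rdf_profile", "data.frame"),
            bin_width = bin_width, r_max = r_max,
            n_frames = length(traj$frames))
}

#' Peak positions of an RDF profile
#'
#' Local maxima with prominence (height above the higher of the two
#' flanking valley minima) at least `min_prominence`, sorted by r.
#'
#' @param profile An `rdf_profile` (or data.frame with `r`, `g`).
#' @param min_prominence Minimum peak prominence in g units.
#' @return Numeric vector of peak positions (possibly empty).
#' @export
peak_positions <- function(profile, min_prominence = 0.5) {
  r <- profile$r; g <- profile$g
  n <- length(g)
  if (n < 3) return(numeric(0))
  out <- numeric(0)
  for (i in 2:(n - 1)) {
    if (g[i] > g[i - 1] && g[i] >= g[i + 1]) {
      lmin <- min(g[1:i]); rmin <- min(g[i:n])
      if (g[i] - max(lmin, rmin) >= min_prominence) out <- c(out, r[i])
    }
  }
  sort(out)
}

#' Stacking-order score from an RDF profile
#'
#' Counts how many consecutive neighbor shells are resolved: for
#' k = 1, 2, ... it requires a detected peak within `tol` of k * rise
#' with height at least `min_height` (above the structureless baseline
#' of 1). An ideal stack with three shells inside r_max scores 3; a
#' disordered strand in which only the nearest neighbor survives
#' scores 1.
#'
#' @param profile An `rdf_profile`.
#' @param rise Expected stacking rise, Angstrom.
#' @param tol Position tolerance, Angstrom.
#' @param min_height Minimum peak height in g units.
#' @param min_prominence Prominence threshold for peak detection.
#' @return List with `score` (integer), `peaks` (positions), `heights`.
#' @export
stacking_order_score <- function(profile, rise = 3.4, tol = 0.6,
                                 min_height = 1.5, min_prominence = 0.5) {
  pk <- peak_positions(profile, min_prominence)
  heights <- profile$g[match(pk, profile$r)]
  keep <- heights >= min_height
  pk <- pk[keep]; heights <- heights[keep]
  r_max <- attr(profile, "r_max")
  if (is.null(r_max)) r_max <- max(profile$r)
  k_max <- floor(r_max / rise)
  score <- 0L
  for (k in seq_len(k_max)) {
    if (any(abs(pk - k * rise) <= tol)) score <- score + 1L else break
  }
  list(score = score, peaks = pk, heights = heights)
}

#' Per-monomer side-chain extension map
#'
#' For every monomer and side-chain endpoint label, the time-averaged
#' Euclidean distance from the monomer's core centroid (mean of its
#' labeled core points) to the endpoint, with a folded / intermediate /
#' extended classification from [classify_folding()].
#'
#' @param traj A `fiber_trajectory`.
#' @param labels Endpoint labels to map; defaults to every non-core
#'   label present.
#' @param folded_below,extended_above Classification thresholds,
#'   Angstrom.
#' @return Object of class `extension_map`: data.frame with columns
#'   `helix`, `index`, `label`, `mean_distance_A`, `class`.
#' @export
side_chain_extension_map <- function(traj, labels = NULL,
                                     folded_below = 20,
                                     extended_above = 25) {
  .traj_check(traj)
  f1 <- traj$frames[[1]]
  if (is.null(labels)) labels <- setdiff(unique(f1$label), "core")
  if (length(labels) == 0 || !all(labels %in% f1$label))
    stop("missing side-chain endpoint label(s)")
  units <- unique(f1[, c("helix", "index")])
  rows <- do.call(rbind, lapply(seq_len(nrow(units)), function(u) {
    h <- units$helix[u]; i <- units$index[u]
    do.call(rbind, lapply(labels, function(lb) {
      d <- vapply(traj$frames, function(fr) {
        sel <- fr$helix == h & fr$index == i
        core <- colMeans(fr[sel & fr$label == "core",
                            c("x", "y", "z"), drop = FALSE])
        ep <- fr[sel & fr$label == lb, c("x", "y", "z"), drop = FALSE]
        if (nrow(ep) == 0) stop("label ", lb, " missing for ", h, ":", i)
        sqrt(sum((as.numeric(ep[1, ]) - core)^2))
      }, numeric(1))
      data.frame(helix = h, index = i, label = lb,
                 mean_distance_A = mean(d), stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  map <- structure(rows, class = c("extension_map", "data.frame"))
  classify_folding(map, folded_below, extended_above)
}

#' Classify side-chain extension distances
#'
#' Folded when the mean core-to-endpoint distance is below
#' `folded_below` (back-folded side chains), extended above
#' `extended_above` (solvent-exposed), intermediate in between.
#'
#' @param map An `extension_map` (column `mean_distance_A`).
#' @param folded_below,extended_above Thresholds in Angstrom,
#'   `folded_below < extended_above`.
#' @return The map with a `class` column.
#' @export
classify_folding <- function(map, folded_below = 20, extended_above = 25) {
  if (folded_below >= extended_above)
    stop("require folded_below < extended_above")
  d <- map$mean_distance_A
  if (any(d < 0)) stop("distances must be >= 0")
  map$class <- ifelse(d < folded_below, "folded",
                      ifelse(d > extended_above, "extended",
                             "intermediate"))
  map
}

#' Write a trajectory as multi-frame labeled XYZ
#'
#' Each frame: a count line, a comment line `frame <i>`, then one line
#' per point `helix:index:label x y z` (full double precision).
#'
#' @param traj A `fiber_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  .traj_check(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(c(as.character(nrow(fr)), paste("frame", i)), con)
    writeLines(sprintf("%s:%d:%s %.17g %.17g %.17g", fr$helix, fr$index,
                       fr$label, fr$x, fr$y, fr$z), con)
  }
  invisible(path)
}

#' Write a trajectory in minimal PDB-like format
#'
#' ATOM records with the endpoint label as atom name, helix as chain
#' (h1 -> A, h2 -> B), monomer index as residue number; frames wrapped
#' in MODEL/ENDMDL. Coordinates keep PDB's 3-decimal precision.
#'
#' @param traj A `fiber_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  .traj_check(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$frames)) {
    fr <- traj$frames[[i]]
    writeLines(sprintf("MODEL %8d", i), con)
    chain <- c(h1 = "A", h2 = "B")[fr$helix]
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f",
      seq_len(nrow(fr)), substr(fr$label, 1, 4), "BTA", chain,
      fr$index, fr$x, fr$y, fr$z), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read a labeled trajectory
#'
#' Reads the multi-frame XYZ written by [write_trajectory_xyz()] (label
#' field `helix:index:label`) or the PDB-like format of
#' [write_trajectory_pdb()].
#'
#' @param path Input path.
#' @param format `"xyz"` or `"pdb"`.
#' @return A `fiber_trajectory` (without ground-truth labels).
#' @export
read_trajectory <- function(path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  lines <- readLines(path)
  frames <- list()
  if (format == "xyz") {
    i <- 1L; fnum <- 0L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      n <- suppressWarnings(as.integer(lines[i]))
      fnum <- fnum + 1L
      if (is.na(n) || i + 1L + n > length(lines))
        stop("malformed or truncated XYZ at frame ", fnum)
      body <- lines[(i + 2L):(i + 1L + n)]
      parts <- strsplit(trimws(body), "[[:space:]]+")
      if (any(lengths(parts) != 4))
        stop("malformed point line in frame ", fnum)
      lab <- strsplit(vapply(parts, `[[`, "", 1), ":", fixed = TRUE)
      if (any(lengths(lab) != 3))
        stop("point label must be helix:index:label (frame ", fnum, ")")
      frames[[fnum]] <- data.frame(
        helix = vapply(lab, `[[`, "", 1),
        index = as.integer(vapply(lab, `[[`, "", 2)),
        label = vapply(lab, `[[`, "", 3),
        x = as.numeric(vapply(parts, `[[`, "", 2)),
        y = as.numeric(vapply(parts, `[[`, "", 3)),
        z = as.numeric(vapply(parts, `[[`, "", 4)),
        stringsAsFactors = FALSE)
      i <- i + 2L + n
    }
  } else {
    fr <- NULL; fnum <- 0L
    for (ln in lines) {
      if (startsWith(ln, "MODEL")) {
        fnum <- fnum + 1L; fr <- list()
      } else if (startsWith(ln, "ATOM")) {
        if (is.null(fr)) stop("ATOM record outside MODEL block")
        fr[[length(fr) + 1L]] <- data.frame(
          helix = c(A = "h1", B = "h2")[trimws(substr(ln, 22, 22))],
          index = as.integer(substr(ln, 23, 26)),
          label = trimws(substr(ln, 13, 16)),
          x = as.numeric(substr(ln, 31, 38)),
          y = as.numeric(substr(ln, 39, 46)),
          z = as.numeric(substr(ln, 47, 54)),
          stringsAsFactors = FALSE)
      } else if (startsWith(ln, "ENDMDL")) {
        frames[[fnum]] <- do.call(rbind, fr); fr <- NULL
      }
    }
    if (!is.null(fr)) stop("truncated PDB: MODEL ", fnum, " not closed")
  }
  if (length(frames) == 0) stop("no frames found in ", path)
  n0 <- nrow(frames[[1]])
  for (k in seq_along(frames))
    if (nrow(frames[[k]]) != n0)
      stop("inconsistent point count at frame ", k)
  structure(list(frames = frames, truth = NULL, config = NULL),
            class = "fiber_trajectory")
}
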