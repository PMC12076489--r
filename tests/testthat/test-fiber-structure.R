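test_that("double-helix geometry matches the stacking design", {
  traj <- build_double_helix_trajectory(
    helix_config(jitter_sd = 0, n_frames = 1))
  fr <- traj$frames[[1]]
  # 9 + 9 monomers, each with a core and three labeled endpoints
  expect_equal(nrow(fr), 18 * 4)
  expect_setequal(unique(fr$helix), c("h1", "h2"))
  # jitter-free nearest-neighbor core distance equals the rise exactly
  for (h in c("h1", "h2")) {
    cores <- fr[fr$label == "core" & fr$helix == h, c("x", "y", "z")]
    d <- as.matrix(dist(cores))
    nn <- apply(d + diag(Inf, nrow(d)), 1, min)
    expect_equal(unname(nn), rep(3.4, 9), tolerance = 1e-12)
  }
  expect_error(helix_config(monomers_per_helix = 0), ">= 1")
  expect_error(helix_config(n_helices = 3), "double helix")
})

test_that("ideal-stack RDF peaks at multiples of the rise", {
  traj <- build_double_helix_trajectory(
    helix_config(jitter_sd = 0, n_frames = 2))
  for (h in c("h1", "h2")) {
    prof <- core_rdf(traj, h, bin_width = 0.1, r_max = 12)
    expect_equal(peak_positions(prof), c(3.4, 6.8, 10.2),
                 tolerance = 1e-9)
    expect_true(all(prof$g >= 0))
    sc <- stacking_order_score(prof)
    expect_equal(sc$score, 3L)
  }
  one <- build_double_helix_trajectory(
    helix_config(monomers_per_helix = 1, n_frames = 1))
  expect_error(core_rdf(one, "h1"), ">= 2 core")
  expect_error(core_rdf(traj, "h1", bin_width = 0), "bin_width")
})

test_that("RDF normalization gives 1 for structureless distances", {
  # uniform-random points whose pairwise distances fill the support:
  # mean g over the histogram range should sit near 1
  set.seed(42)
  frames <- lapply(1:40, function(i) {
    n <- 25
    data.frame(helix = "h1", index = seq_len(n), label = "core",
               x = runif(n, 0, 30), y = 0, z = 0,
               stringsAsFactors = FALSE)
  })
  traj <- structure(list(frames = frames, truth = NULL, config = NULL),
                    class = "fiber_trajectory")
  prof <- core_rdf(traj, "h1", bin_width = 0.5, r_max = 25)
  expect_equal(mean(prof$g), 1, tolerance = 0.05)
})

test_that("jitter degrades the stacking order monotonically", {
  score_at <- function(j) {
    traj <- build_double_helix_trajectory(
      helix_config(jitter_sd = j, n_frames = 100, seed = 7))
    prof <- core_rdf(traj, "h1", 0.1, 12)
    stacking_order_score(prof)$score
  }
  expect_equal(score_at(0), 3L)
  expect_lt(score_at(2), 3L)
  # third-shell peak height shrinks with jitter while the first persists
  h_at <- function(j, r0) {
    traj <- build_double_helix_trajectory(
      helix_config(jitter_sd = j, n_frames = 100, seed = 7))
    prof <- core_rdf(traj, "h1", 0.1, 12)
    max(prof$g[abs(prof$r - r0) <= 0.6])
  }
  expect_gt(h_at(0.8, 3.4), 1.5)
  expect_lt(h_at(0.8, 10.2), h_at(0, 10.2))
  # flat profile: no peaks, score 0
  flat <- structure(data.frame(r = seq(0.1, 12, 0.1), g = 1),
                    class = c("rdf_profile", "data.frame"),
                    bin_width = 0.1, r_max = 12, n_frames = 1)
  expect_equal(peak_positions(flat), numeric(0))
  expect_equal(stacking_order_score(flat)$score, 0L)
})

test_that("prominence filtering keeps only strong peaks", {
  r <- seq(0.1, 12, 0.1)
  g <- 1 + 5 * exp(-(r - 3.4)^2 / 0.02) + 0.4 * exp(-(r - 6.8)^2 / 0.02)
  prof <- structure(data.frame(r = r, g = g),
                    class = c("rdf_profile", "data.frame"))
  expect_equal(peak_positions(prof, min_prominence = 1), 3.4,
               tolerance = 0.05)
  expect_equal(length(peak_positions(prof, min_prominence = 0.2)), 2)
})

test_that("extension map distances classify against generator truth", {
  traj <- build_double_helix_trajectory(
    helix_config(jitter_sd = 1, n_frames = 20, folded_fraction = 0.3,
                 seed = 3))
  map <- side_chain_extension_map(traj)
  expect_s3_class(map, "extension_map")
  expect_equal(nrow(map), 18 * 3)
  merged <- merge(map, traj$truth, by = c("helix", "index"))
  acc <- mean(merged$class == merged$fold)
  expect_gte(acc, 0.95)
  # all-extended generator: every chain classified extended
  ext <- build_double_helix_trajectory(
    helix_config(jitter_sd = 0.5, n_frames = 10, folded_fraction = 0))
  mext <- side_chain_extension_map(ext)
  expect_true(all(mext$class == "extended"))
  expect_error(side_chain_extension_map(traj, labels = "missing"),
               "label")
})

test_that("folding thresholds split at 20 and 25 Angstrom", {
  map <- structure(data.frame(helix = "h1", index = 1:3, label = "NHD",
                              mean_distance_A = c(18, 27, 22)),
                   class = c("extension_map", "data.frame"))
  out <- classify_folding(map)
  expect_equal(out$class, c("folded", "extended", "intermediate"))
  expect_error(classify_folding(map, folded_below = 30,
                                extended_above = 25), "folded_below")
})

test_that("extension map is invariant under rigid motion of every frame", {
  traj <- build_double_helix_trajectory(
    helix_config(jitter_sd = 0.3, n_frames = 5, folded_fraction = 0.4,
                 seed = 9))
  map0 <- side_chain_extension_map(traj)
  # rotate about z by 40 degrees and translate
  th <- 40 * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  traj2 <- traj
  traj2$frames <- lapply(traj$frames, function(fr) {
    xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% rot
    fr$x <- xyz[, 1] + 100; fr$y <- xyz[, 2] - 50; fr$z <- xyz[, 3] + 7
    fr
  })
  map2 <- side_chain_extension_map(traj2)
  expect_equal(map2$mean_distance_A, map0$mean_distance_A,
               tolerance = 1e-9)
})

test_that("trajectories round-trip through XYZ and PDB-like formats", {
  traj <- build_double_helix_trajectory(
    helix_config(jitter_sd = 0.2, n_frames = 3, folded_fraction = 0.5))
  fx <- tempfile(fileext = ".xyz")
  write_trajectory_xyz(traj, fx)
  rx <- read_trajectory(fx, "xyz")
  expect_equal(length(rx$frames), 3)
  for (i in 1:3)
    expect_equal(rx$frames[[i]], traj$frames[[i]], tolerance = 1e-12)
  # same content through the PDB-like writer (3-decimal coordinates)
  fp <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, fp)
  rp <- read_trajectory(fp, "pdb")
  expect_identical(rp$frames[[1]]$label, traj$frames[[1]]$label)
  expect_identical(rp$frames[[1]]$helix, traj$frames[[1]]$helix)
  expect_equal(rp$frames[[1]]$x, traj$frames[[1]]$x, tolerance = 6e-4)
  # metrics agree across formats
  expect_equal(side_chain_extension_map(rp)$mean_distance_A,
               side_chain_extension_map(traj)$mean_distance_A,
               tolerance = 1e-2)
  # truncated file errors with the frame number
  lines <- readLines(fx)
  writeLines(lines[1:(length(lines) - 10)], fx)
  expect_error(read_trajectory(fx, "xyz"), "frame")
})
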