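#!/usr/bin/env Rscript
# Stacking order and side-chain back-folding metrics on synthetic
# double-helix trajectories: per-helix core g(r), stacking-order
# scores, and per-unit extension maps with folded/extended labels.

suppressPackageStartupMessages(library(suprafiber))
dir.create("results", showWarnings = FALSE)
seed <- 1L

## ordered reference fiber: 9+9 monomers, 3.4 A rise, no disorder
ideal <- build_double_helix_trajectory(
  helix_config(jitter_sd = 0, n_frames = 10, seed = seed))
## disordered copolymer-like fiber: positional jitter + back-folding
disord <- build_double_helix_trajectory(
  helix_config(jitter_sd = 1, n_frames = 100, folded_fraction = 0.33,
               seed = seed))

for (nm in c("h1", "h2")) {
  p_i <- core_rdf(ideal, nm, bin_width = 0.1, r_max = 12)
  p_d <- core_rdf(disord, nm, bin_width = 0.1, r_max = 12)
  write.csv(as.data.frame(p_i), sprintf("results/rdf_ideal_%s.csv", nm),
            row.names = FALSE)
  write.csv(as.data.frame(p_d),
            sprintf("results/rdf_disordered_%s.csv", nm),
            row.names = FALSE)
  cat(sprintf(
    "helix %s: ideal g(r) peaks at %s A (stacking score %d); disordered score %d\n",
    nm, paste(round(peak_positions(p_i), 1), collapse = "/"),
    stacking_order_score(p_i)$score, stacking_order_score(p_d)$score))
}
cat("Ideal stacks show the three characteristic neighbor peaks at",
    "3.4/6.8/10.2 A;\npositional disorder suppresses the higher shells",
    "first.\n\n")

## side-chain extension and folded/extended classification
map <- side_chain_extension_map(disord)
write.csv(as.data.frame(map), "results/extension_map.csv",
          row.names = FALSE)
merged <- merge(map, disord$truth, by = c("helix", "index"))
acc <- mean(merged$class == merged$fold)
cat(sprintf(
  "Extension map over %d side chains: %d folded (<20 A), %d extended (>25 A), %d intermediate;\nagreement with generator ground truth %.1f%%.\n",
  nrow(map), sum(map$class == "folded"),
  sum(map$class == "extended"), sum(map$class == "intermediate"),
  100 * acc))

## trajectory excerpt (first 10 frames) for downstream tools
excerpt <- disord
excerpt$frames <- excerpt$frames[1:10]
write_trajectory_xyz(excerpt, "results/fiber_trajectory.xyz")
cat("Wrote a 10-frame labeled XYZ excerpt to results/fiber_trajectory.xyz\n")
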