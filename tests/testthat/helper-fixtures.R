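# shared fixtures built in code at test time

table1_row <- function(monomer) {
  tbl <- exchange_parameter_table()
  as.list(tbl[tbl$monomer == monomer, ])
}

small_image_config <- function(size = 96,
                               fiber_paths = default_fiber_paths(size),
                               ...) {
  image_sim_config(size = size, fiber_paths = fiber_paths, ...)
}

# independent per-atom mass oracle: explicit atom-by-atom summation from
# a literal table, not via the package's mass_table() accessor paths
oracle_masses <- function(counts) {
  w <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999)
  m <- c(C = 12.0, H = 1.00782503207, N = 14.00307400443,
         O = 15.99491461957)
  avg <- 0; mono <- 0
  for (el in names(counts)) {
    for (i in seq_len(counts[[el]])) {
      avg <- avg + w[[el]]
      mono <- mono + m[[el]]
    }
  }
  list(average = avg, monoisotopic = mono)
}
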