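# small parameter sets shared across tests; tight relaxation where a test
# asserts equilibrium geometry
tight_params <- function(...) {
  simulation_params(relax_tol_factor = 1e-7, max_substeps = 10000, ...)
}

# random snapshot of n cells in a box, radii in [0.65, 1] * r_max
random_snapshot <- function(n, r_max = 7, box = 60, seed = 1) {
  with_seed(seed, {
    cells <- data.frame(
      id = seq_len(n),
      x = runif(n, -box, box), y = runif(n, -box, box),
      z = runif(n, -box, box),
      radius = runif(n, 0.65 * r_max, r_max))
    organoid_snapshot(cells)
  })
}

# all-pairs reference forces via the exported scalar operations
net_forces_ref <- function(snapshot, params) {
  pos <- as.matrix(snapshot$cells[, c("x", "y", "z")])
  rad <- snapshot$cells$radius
  n <- nrow(pos)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    out[i, ] <- total_force(pos[i, ], rad[i], pos[-i, , drop = FALSE],
                            rad[-i], params)
  }
  out
}
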