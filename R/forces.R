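#' Pairwise repulsive spring force between two cells
#'
#' Hookean repulsion acting on cell i when the center distance falls below
#' the rest length `r_i + r_j` (the sum of the current radii).  Zero at or
#' beyond contact.  The force on j is the exact negative (antisymmetry).
#'
#' @param x_i,x_j 3-vectors, cell center positions (micrometers).
#' @param r_i,r_j current cell radii (micrometers).
#' @param f_rep spring stiffness.
#' @return 3-vector force on cell i, pointing from j toward i when active.
#' @export
#' @examples
#' repulsive_force(c(0, 0, 0), c(10, 0, 0), 7, 7, f_rep = 1)  # 4 * (-1, 0, 0)
repulsive_force <- function(x_i, x_j, r_i, r_j, f_rep) {
  dvec <- x_i - x_j
  d <- sqrt(sum(dvec^2))
  rest <- r_i + r_j
  if (d >= rest) return(c(0, 0, 0))
  if (d < 1e-12) {
    warning("coincident cell centers: resolving with a random direction")
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    return(f_rep * rest * u)
  }
  f_rep * (rest - d) * dvec / d
}

#' Pairwise adhesive spring force between two cells
#'
#' Attraction restoring the rest length `2 r_max`, active only inside the
#' window `(2 r_max, 2.25 r_max)` so cells that drift apart are pulled back
#' while distant cells are unaffected.
#'
#' @inheritParams repulsive_force
#' @param f_adh spring stiffness.
#' @param r_max maximal cell radius (micrometers).
#' @return 3-vector force on cell i (attractive: points from i toward j).
#' @export
adhesive_force <- function(x_i, x_j, f_adh, r_max) {
  dvec <- x_i - x_j
  d <- sqrt(sum(dvec^2))
  if (d <= 2 * r_max || d >= 2.25 * r_max) return(c(0, 0, 0))
  f_adh * (2 * r_max - d) * dvec / d
}

#' Net spring force on one cell from a set of neighbors
#'
#' Sum of the pairwise repulsive and adhesive contributions.  This is the
#' plain all-pairs reference; the simulator's grid-accelerated force kernel
#' is required to agree with it exactly.
#'
#' @param x_i 3-vector, position of the focal cell.
#' @param r_i radius of the focal cell.
#' @param neighbor_pos N x 3 matrix of neighbor positions (excluding the
#'   focal cell).
#' @param neighbor_radius numeric vector of neighbor radii.
#' @param params a [simulation_params()] object.
#' @return 3-vector net force (in units of `eta`).
#' @export
total_force <- function(x_i, r_i, neighbor_pos, neighbor_radius, params) {
  f <- c(0, 0, 0)
  if (is.null(neighbor_pos) || NROW(neighbor_pos) == 0) return(f)
  neighbor_pos <- matrix(neighbor_pos, ncol = 3)
  for (j in seq_len(nrow(neighbor_pos))) {
    f <- f + repulsive_force(x_i, neighbor_pos[j, ], r_i,
                             neighbor_radius[j], params$f_rep / params$eta) +
      adhesive_force(x_i, neighbor_pos[j, ], params$f_adh / params$eta,
                     params$r_max)
  }
  f
}

#' Overdamped position update
#'
#' Explicit Euler step of the overdamped equation of motion:
#' `X(t + dt) = X(t) + dt * F / eta`.  No velocity state is kept.
#'
#' @param x 3-vector (or N x 3 matrix) of positions.
#' @param force matching force vector/matrix.
#' @param eta damping coefficient.
#' @param dt time step, hours.
#' @return updated positions, same shape as `x`.
#' @export
relocate <- function(x, force, eta, dt) {
  stopifnot(dt > 0, eta > 0)
  x + dt * force / eta
}

#' Net forces on every cell of a snapshot (grid-accelerated)
#'
#' @param snapshot an `organoid_snapshot`.
#' @param params a [simulation_params()] object.
#' @return N x 3 matrix of forces in units of `eta`.
#' @export
net_forces <- function(snapshot, params) {
  pos <- cell_positions(snapshot)
  .osim_net_forces(pos, snapshot$cells$radius, params$r_max,
                   params$f_rep / params$eta, params$f_adh / params$eta)
}

#' Relax a snapshot to mechanical equilibrium
#'
#' Repeats force evaluation and overdamped relocation sub-steps until the
#' largest single-cell displacement in a sub-step drops below
#' `relax_tol_factor * r_max`, or `max_substeps` is reached (with a warning:
#' this signals mis-tuned `dt_mech`/stiffness).
#'
#' @param snapshot an `organoid_snapshot`.
#' @param params a [simulation_params()] object.
#' @return the snapshot with updated positions; attributes `substeps` and
#'   `converged` report the relaxation effort.
#' @export
relax_snapshot <- function(snapshot, params) {
  if (n_cells(snapshot) < 2) {
    attr(snapshot, "substeps") <- 0L
    attr(snapshot, "converged") <- TRUE
    return(snapshot)
  }
  res <- .osim_relax(cell_positions(snapshot), snapshot$cells$radius,
                     params$r_max, params$f_rep / params$eta,
                     params$f_adh / params$eta, params$dt_mech,
                     params$relax_tol_factor * params$r_max,
                     params$max_substeps)
  if (!res$converged) {
    warning(sprintf(
      "mechanical relaxation hit the sub-step cap (%d) at t = %g h",
      params$max_substeps, snapshot$time))
  }
  if (res$n_coincident > 0) {
    warning(sprintf("%d coincident cell pair(s) resolved with random directions",
                    res$n_coincident))
  }
  snapshot$cells$x <- res$positions[, 1]
  snapshot$cells$y <- res$positions[, 2]
  snapshot$cells$z <- res$positions[, 3]
  attr(snapshot, "substeps") <- res$substeps
  attr(snapshot, "converged") <- res$converged
  snapshot
}
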