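#' Cell-cycle phase from fractional age
#'
#' The lifespan of each cell is split into the four mammalian cell-cycle
#' phases as fixed fractions of its individual division age: G1 for the
#' first 45%, S for the next 35%, G2 for the next 15% and M for the final
#' 5%.  The mapping is deterministic in `age / div_age`.
#'
#' @param age current age(s), hours.
#' @param div_age individual division age(s), hours.
#' @param phase_fractions four fractions summing to 1 (G1, S, G2, M).
#' @return character vector of phases.
#' @export
#' @examples
#' cell_phase(c(0, 9, 16, 19, 20), 20)  # G1 G1 S G2 M  (boundaries at 45/80/95%)
cell_phase <- function(age, div_age,
                       phase_fractions = c(G1 = 0.45, S = 0.35,
                                           G2 = 0.15, M = 0.05)) {
  ratio <- age / div_age
  cuts <- cumsum(phase_fractions)[1:3]
  out <- character(length(ratio))
  out[ratio < cuts[1]] <- "G1"
  out[ratio >= cuts[1] & ratio < cuts[2]] <- "S"
  out[ratio >= cuts[2] & ratio < cuts[3]] <- "G2"
  out[ratio >= cuts[3]] <- "M"
  out
}

#' Cell radius as a function of age
#'
#' Cells are born at `birth_radius_factor * r_max` and grow linearly with age
#' to `r_max`.  Under the default `"g2"` schedule growth completes at the end
#' of G2 (95% of the lifespan), reflecting that growth happens predominantly
#' in G1 but can continue through G2; the `"g1"` alternative completes growth
#' at the end of G1.  The radius never exceeds `r_max`.
#'
#' This maps the cycle age of a non-arrested cell to its radius.  Under the
#' default `arrest_growth = "continue"` policy, arrested cells keep growing
#' at the same linear rate even though their cycle age is frozen (see
#' [advance_cycle()]), so their radius can exceed the value implied by their
#' age.
#'
#' @param age current age(s), hours.
#' @param div_age individual division age(s), hours.
#' @param params a [simulation_params()] object.
#' @return numeric vector of radii, micrometers.
#' @export
cell_radius_at_age <- function(age, div_age, params) {
  gf <- switch(params$growth_schedule,
               g2 = sum(params$phase_fractions[c("G1", "S", "G2")]),
               g1 = params$phase_fractions[["G1"]])
  frac <- pmin(1, pmax(0, age / (gf * div_age)))
  params$r_max * (params$birth_radius_factor +
                    (1 - params$birth_radius_factor) * frac)
}

# linear radius growth rate (um/h) of a cell with the given division age
radius_growth_rate <- function(div_age, params) {
  gf <- switch(params$growth_schedule,
               g2 = sum(params$phase_fractions[c("G1", "S", "G2")]),
               g1 = params$phase_fractions[["G1"]])
  (1 - params$birth_radius_factor) * params$r_max / (gf * div_age)
}

#' Contact-inhibition state of every cell
#'
#' A cell is contact-inhibited while the number of other cells whose centers
#' lie strictly within two cell diameters (`4 * r_max`, using the maximal
#' radius) exceeds `n_neigh`.  Arrested cells stay metabolically present but
#' their cell-cycle clock is frozen: arrest time does not count toward any
#' phase.
#'
#' @param snapshot an `organoid_snapshot`.
#' @param params a [simulation_params()] object.
#' @return list with `inhibited` (logical vector) and `n_neighbors`
#'   (integer vector), in snapshot row order.
#' @export
#' @examples
#' snap <- make_fixture("pair", r = 7)
#' contact_inhibited(snap, simulation_params(n_neigh = 0))$inhibited
contact_inhibited <- function(snapshot, params) {
  n <- neighbor_counts(cell_positions(snapshot), snapshot$cells$radius,
                       params)
  list(inhibited = n > params$n_neigh, n_neighbors = n)
}

# neighbor counts under the configured inhibition scope
neighbor_counts <- function(pos, radius, params) {
  if (identical(params$inhibition_scope, "current")) {
    .osim_count_neighbors_vec(pos, 4 * radius)
  } else {
    .osim_count_neighbors(pos, params$inhibition_radius)
  }
}

#' Advance the cell cycle of non-arrested cells by one time step
#'
#' Ages every non-arrested cell by `dt` and refreshes the radius and phase
#' columns.  Arrest freezes the cycle clock: age and phase of arrested cells
#' never advance, and arrest time does not count toward any phase.  Under
#' the default `arrest_growth = "continue"` policy arrested cells still grow
#' their radius toward `r_max` at their linear growth rate (they stay
#' metabolically active); with `"freeze"` their radius is frozen too.
#'
#' @param snapshot an `organoid_snapshot` whose `arrested` column is current.
#' @param dt time step, hours.
#' @param params a [simulation_params()] object.
#' @return the updated snapshot.
#' @export
advance_cycle <- function(snapshot, dt, params) {
  cells <- snapshot$cells
  active <- !cells$arrested
  cells$age[active] <- cells$age[active] + dt
  grow <- if (identical(params$arrest_growth, "continue")) {
    rep(TRUE, nrow(cells))
  } else {
    active
  }
  cells$radius[grow] <- pmin(
    params$r_max,
    cells$radius[grow] + dt * radius_growth_rate(cells$div_age[grow], params))
  cells$phase[active] <- cell_phase(cells$age[active], cells$div_age[active],
                                    params$phase_fractions)
  snapshot$cells <- cells
  snapshot
}

#' Divide one cell into two daughters
#'
#' Daughters are placed symmetrically around the mother's center at
#' `+/- daughter_offset_factor * r_max` along a random axis; by default the
#' polar angle is drawn uniformly on `[0, pi]` and the azimuthal angle
#' uniformly on `[0, 2 pi)` (set `division_axis = "area"` in the parameters
#' for area-uniform axes).  Each daughter starts at age 0 with radius
#' `birth_radius_factor * r_max` and an individual division age
#' `a_div * (1 + U)`, `U ~ Uniform(-noise_frac, noise_frac)`.  Because the
#' daughters sit closer than the sum of their birth radii, repulsion between
#' them is active immediately.
#'
#' @param cell a single-row data frame (one row of a snapshot's `cells`).
#' @param params a [simulation_params()] object.
#' @param ids integer ids for the two daughters.
#' @return a two-row data frame of daughter cells.
#' @export
divide_cell <- function(cell, params, ids = cell$id * 2L + c(0L, 1L)) {
  stopifnot(nrow(cell) == 1L)
  make_daughters(cell, params, ids)
}

# vectorized daughter construction for all mothers dividing in one step;
# all placements are computed from the pre-step configuration so the result
# does not depend on mother order
make_daughters <- function(mothers, params, ids) {
  m <- nrow(mothers)
  theta <- switch(params$division_axis,
                  polar = runif(m, 0, pi),
                  area = acos(runif(m, -1, 1)))
  phi <- runif(m, 0, 2 * pi)
  axis <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  offset <- params$daughter_offset_factor * params$r_max * axis
  div_age <- params$a_div * (1 + runif(2 * m, -params$noise_frac,
                                       params$noise_frac))
  center <- as.matrix(mothers[, c("x", "y", "z")])
  pos <- rbind(center + offset, center - offset)
  data.frame(
    id = as.integer(ids),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    radius = params$birth_radius_factor * params$r_max,
    phase = "G1",
    age = 0,
    div_age = div_age,
    arrested = FALSE,
    n_neighbors = NA_integer_
  )
}
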