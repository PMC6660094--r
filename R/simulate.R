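# internal mutable state mirrors the snapshot columns but keeps positions as
# a matrix so the compiled kernels can be called without conversion overhead
state_from_snapshot <- function(snapshot) {
  cells <- snapshot$cells
  list(id = cells$id,
       pos = cell_positions(snapshot),
       radius = cells$radius,
       age = cells$age,
       div_age = cells$div_age,
       arrested = cells$arrested,
       time = snapshot$time)
}

state_to_snapshot <- function(state, params) {
  ci <- neighbor_counts(state$pos, state$radius, params)
  cells <- data.frame(
    id = state$id,
    x = state$pos[, 1], y = state$pos[, 2], z = state$pos[, 3],
    radius = state$radius,
    phase = cell_phase(pmin(state$age / state$div_age, 1) * state$div_age,
                       state$div_age, params$phase_fractions),
    age = state$age,
    div_age = state$div_age,
    arrested = ci > params$n_neigh,
    n_neighbors = as.integer(ci)
  )
  organoid_snapshot(cells, time = state$time)
}

# one biology step of dt: (1) refresh neighbor counts and arrest flags,
# (2) age non-arrested cells, (3) simultaneous divisions decided from the
# pre-step configuration, (4) mechanical relaxation to quasi-equilibrium
step_state <- function(state, params) {
  n <- length(state$id)
  counts <- neighbor_counts(state$pos, state$radius, params)
  arrested <- counts > params$n_neigh
  if (identical(params$arrest_mode, "gate")) {
    # crowding gates the division event only; the clock keeps running but
    # a crowded cell parks at its division age (age does not overshoot)
    state$age <- pmin(state$age + params$dt,
                      ifelse(arrested, pmax(state$div_age, state$age),
                             Inf))
  } else {
    state$age[!arrested] <- state$age[!arrested] + params$dt
  }
  active <- !arrested
  grow <- if (identical(params$arrest_growth, "continue")) {
    rep(TRUE, n)
  } else {
    active
  }
  state$radius[grow] <- pmin(
    params$r_max,
    state$radius[grow] +
      params$dt * radius_growth_rate(state$div_age[grow], params))

  eligible <- which(active & state$age >= state$div_age - 1e-9)
  if (length(eligible) > 0) {
    mothers <- data.frame(
      id = state$id[eligible],
      x = state$pos[eligible, 1],
      y = state$pos[eligible, 2],
      z = state$pos[eligible, 3])
    ids <- max(state$id) + seq_len(2L * length(eligible))
    daughters <- make_daughters(mothers, params, ids)
    keep <- setdiff(seq_len(n), eligible)
    state$id <- c(state$id[keep], daughters$id)
    state$pos <- rbind(state$pos[keep, , drop = FALSE],
                       as.matrix(daughters[, c("x", "y", "z")]))
    state$radius <- c(state$radius[keep], daughters$radius)
    state$age <- c(state$age[keep], daughters$age)
    state$div_age <- c(state$div_age[keep], daughters$div_age)
    state$arrested <- c(arrested[keep], daughters$arrested)
  } else {
    state$arrested <- arrested
  }

  if (length(state$id) > 1) {
    res <- .osim_relax(state$pos, state$radius, params$r_max,
                       params$f_rep / params$eta, params$f_adh / params$eta,
                       params$dt_mech,
                       params$relax_tol_factor * params$r_max,
                       params$max_substeps)
    if (!res$converged) {
      warning(sprintf(
        "relaxation sub-step cap (%d) hit at t = %g h with %d cells",
        params$max_substeps, state$time, length(state$id)))
    }
    state$pos <- res$positions
  }
  if (any(!is.finite(state$pos))) {
    stop(sprintf("non-finite cell positions at t = %g h; aborting",
                 state$time + params$dt))
  }
  state$time <- state$time + params$dt
  state
}

#' Advance a snapshot by one biology step
#'
#' Applies, in this fixed order: (1) recompute neighbor counts and arrest
#' flags for all cells; (2) advance the cell cycle of non-arrested cells;
#' (3) divide every eligible cell simultaneously (placements are computed
#' from the pre-step configuration, so the result does not depend on cell
#' order); (4) mechanical relaxation by repeated force/relocate sub-steps
#' until the largest per-cell displacement falls below
#' `relax_tol_factor * r_max`.
#'
#' Uses R's global random number stream; seed it (or use [run_simulation()],
#' which manages seeding) for reproducibility.
#'
#' @param snapshot an `organoid_snapshot`.
#' @param params a [simulation_params()] object.
#' @return the snapshot one `dt` later.
#' @export
simulate_step <- function(snapshot, params) {
  state <- state_from_snapshot(snapshot)
  state <- step_state(state, params)
  state_to_snapshot(state, params)
}

#' Run a full organoid growth simulation
#'
#' Starts from a single founder cell at the origin (age 0, radius
#' `birth_radius_factor * r_max`, phase G1, division age
#' `a_div * (1 + U)`) and advances in biology steps of `dt` until `t_end`,
#' emitting snapshots at the requested output times.  The trajectory is
#' fully determined by `seed`.
#'
#' @param params a [simulation_params()] object.
#' @param seed global seed; defaults to `params$seed`.  The simulation
#'   stream is derived from it with [derive_seed()].
#' @param output_times times (hours) at which snapshots are emitted;
#'   default: daily plus the final time.
#' @param stop_fn optional `function(snapshot) -> logical`; evaluated at
#'   every output time, and the run is truncated when it returns `TRUE`
#'   (used by the sweep to abandon runs that have already left the
#'   reference growth band).
#' @return an object of class `organoid_trajectory`: list with `snapshots`
#'   (one `organoid_snapshot` per emitted time), `times`, `n_cells`,
#'   `params`, `seed` and `truncated`.
#' @export
#' @examples
#' p <- simulation_params(t_end = 24, a_div = 11)
#' traj <- run_simulation(p, seed = 1)
#' traj$n_cells
run_simulation <- function(params, seed = params$seed, output_times = NULL,
                           stop_fn = NULL) {
  if (is.null(output_times)) {
    output_times <- unique(sort(c(seq(0, params$t_end, by = 24),
                                  params$t_end)))
  }
  output_times <- unique(sort(output_times))
  if (any(output_times < 0 | output_times > params$t_end + 1e-9)) {
    stop("output_times must lie within [0, t_end]")
  }

  with_seed(derive_seed(seed, "simulation"), {
    founder_div_age <- params$a_div *
      (1 + runif(1, -params$noise_frac, params$noise_frac))
    state <- list(id = 1L,
                  pos = matrix(0, nrow = 1, ncol = 3),
                  radius = params$birth_radius_factor * params$r_max,
                  age = 0,
                  div_age = founder_div_age,
                  arrested = FALSE,
                  time = 0)

    snapshots <- list()
    times <- numeric(0)
    ncells <- integer(0)
    truncated <- FALSE
    next_out <- 1L
    emit <- function(state) {
      snap <- state_to_snapshot(state, params)
      snapshots[[length(snapshots) + 1L]] <<- snap
      times[length(times) + 1L] <<- state$time
      ncells[length(ncells) + 1L] <<- n_cells(snap)
      if (!is.null(stop_fn) && isTRUE(stop_fn(snap))) {
        truncated <<- TRUE
      }
    }

    nsteps <- ceiling(params$t_end / params$dt - 1e-9)
    while (next_out <= length(output_times) &&
           output_times[next_out] <= 1e-9) {
      emit(state)
      next_out <- next_out + 1L
    }
    for (k in seq_len(nsteps)) {
      state <- step_state(state, params)
      state$time <- k * params$dt  # avoid drift in accumulated time
      while (!truncated && next_out <= length(output_times) &&
             state$time >= output_times[next_out] - 1e-9) {
        emit(state)
        next_out <- next_out + 1L
      }
      if (truncated) break
    }

    structure(list(snapshots = snapshots, times = times, n_cells = ncells,
                   params = params, seed = seed, truncated = truncated),
              class = "organoid_trajectory")
  })
}

#' @export
print.organoid_trajectory <- function(x, ...) {
  cat(sprintf(
    "Organoid trajectory: %d snapshot(s), t = %g..%g h, final N = %d%s\n",
    length(x$snapshots), min(x$times), max(x$times),
    x$n_cells[length(x$n_cells)],
    if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Extract the snapshot closest to a requested time
#'
#' @param trajectory an `organoid_trajectory`.
#' @param time_h requested time, hours.
#' @param tol matching tolerance, hours.
#' @return an `organoid_snapshot`.
#' @export
snapshot_at <- function(trajectory, time_h, tol = 1e-6) {
  i <- which(abs(trajectory$times - time_h) <= tol)
  if (length(i) == 0) {
    stop(sprintf("no snapshot at t = %g h (available: %s)", time_h,
                 paste(trajectory$times, collapse = ", ")))
  }
  trajectory$snapshots[[i[1]]]
}

#' Per-snapshot morphometrics of a trajectory
#'
#' @param trajectory an `organoid_trajectory`.
#' @param asa_points Monte-Carlo points per cell for the ASA estimate.
#' @param seed seed for the ASA sampling stream; defaults to the
#'   trajectory's own seed (sub-stream `"asa"`).
#' @return data frame with columns `time_h`, `n_cells`, `D_um`, `RGYR_um`,
#'   `ASA_um2` and `ASA_1e4_um2`.
#' @export
trajectory_summary <- function(trajectory, asa_points = 500,
                               seed = trajectory$seed) {
  rows <- lapply(trajectory$snapshots, function(snap) {
    morphometrics(snap, asa_points = asa_points,
                  seed = derive_seed(seed, "asa"))
  })
  do.call(rbind, rows)
}
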