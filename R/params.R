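#' Simulation parameters for the organoid growth model
#'
#' Collects every constant of the agent-based model.  The three biological
#' parameters varied in the morphochart studies are the maximal cell radius
#' `r_max`, the base division age `a_div` and the contact-inhibition neighbor
#' threshold `n_neigh`; the remaining entries are mechanical and numerical
#' constants with documented defaults.
#'
#' Forces are expressed in units of the damping coefficient `eta`: only the
#' ratios `f_rep/eta` and `f_adh/eta` (units 1/h) enter the overdamped update
#' `X(t + dt) = X(t) + dt * F/eta`, so the defaults keep `eta = 1` and choose
#' the stiffnesses so that the residual overlap after one biology step is a
#' small fraction of the cell radius.  Adhesion is an order of magnitude
#' weaker than repulsion, reflecting its role of loose cohesion rather than
#' volume exclusion.
#'
#' @param r_max maximal (mature) cell radius, micrometers.  Cells are born at
#'   `birth_radius_factor * r_max` and grow to `r_max`.
#' @param a_div base cell division age, hours.  Each daughter receives
#'   `a_div * (1 + U)` with `U ~ Uniform(-noise_frac, noise_frac)`.
#' @param n_neigh contact-inhibition threshold: a cell arrests while the
#'   number of other cells within two cell diameters (`4 * r_max`) exceeds
#'   `n_neigh`.  Use `Inf` to disable contact inhibition.
#' @param f_rep repulsive spring stiffness (per unit `eta`), 1/h.
#' @param f_adh adhesive spring stiffness (per unit `eta`), 1/h.
#' @param eta damping coefficient of the overdamped dynamics.
#' @param dt biology time step, hours.
#' @param dt_mech mechanical relaxation sub-step, hours.  Must satisfy
#'   `dt_mech * f_rep / eta < 1` so an overlapping pair cannot overshoot its
#'   spring equilibrium in a single sub-step.
#' @param noise_frac half-width of the uniform division-age jitter as a
#'   fraction of `a_div`; breaks division synchrony.
#' @param phase_fractions fractions of the lifespan spent in G1, S, G2 and M;
#'   must sum to 1.
#' @param birth_radius_factor radius of a newborn cell relative to `r_max`.
#' @param daughter_offset_factor half-separation of the two daughters at
#'   division, relative to `r_max`.
#' @param t_end simulated time horizon, hours (336 h = 14 days).
#' @param seed default global seed for [run_simulation()].
#' @param growth_schedule `"g2"` (default): the radius grows linearly with age
#'   from `birth_radius_factor * r_max` to `r_max` at the end of G2 (95% of
#'   the lifespan); `"g1"`: growth completes at the end of G1.
#' @param inhibition_scope `"current"` (default): each cell surveys two of
#'   its own current diameters, `4 * radius_i`, so newborn cells see a
#'   smaller neighborhood until they mature; `"r_max"`: the fixed ball of
#'   two maximal diameters, `4 * r_max`, for every cell.
#' @param arrest_mode `"clock"` (default): contact inhibition freezes the
#'   whole cell-cycle clock, so an arrested cell resumes the phase it was in
#'   once the crowding clears; `"gate"`: only the division event is gated —
#'   the cycle clock keeps running, a crowded cell parks when it reaches its
#'   division age and divides as soon as its neighborhood thins out.  Under
#'   both policies arrest time does not count toward the length of any
#'   cycle phase.
#' @param arrest_growth `"continue"` (default): contact-inhibited cells keep
#'   growing their radius toward `r_max` at the same linear rate — arrest
#'   halts the cycle clock, not cell metabolism — so crowded regions of
#'   small newborn cells mechanically loosen as their cells mature, letting
#'   neighbor counts fall back below the threshold; `"freeze"`: arrest also
#'   freezes the radius, so a cell arrested at birth stays at its birth size
#'   for as long as it is crowded.
#' @param division_axis `"polar"` (default): the division axis polar angle is
#'   uniform on `[0, pi]`; `"area"`: area-uniform directions on the sphere.
#' @param relax_tol_factor mechanical relaxation stops once the largest
#'   single-cell displacement in a sub-step falls below
#'   `relax_tol_factor * r_max`.
#' @param max_substeps cap on relaxation sub-steps per biology step; hitting
#'   the cap raises a warning (a sign of mis-tuned `dt_mech`/stiffness).
#'
#' @return an object of class `simulation_params` (a validated named list
#'   with derived fields `adhesion_window` = `(2 r_max, 2.25 r_max)` and
#'   `inhibition_radius` = `4 r_max`).
#' @export
#' @examples
#' p <- simulation_params(r_max = 7, a_div = 11, n_neigh = 6)
#' p$adhesion_window
simulation_params <- function(r_max = 7,
                              a_div = 11,
                              n_neigh = 6,
                              f_rep = 10,
                              f_adh = 0.1,
                              eta = 1,
                              dt = 0.1,
                              dt_mech = 0.02,
                              noise_frac = 0.05,
                              phase_fractions = c(G1 = 0.45, S = 0.35,
                                                  G2 = 0.15, M = 0.05),
                              birth_radius_factor = 0.65,
                              daughter_offset_factor = 0.5,
                              t_end = 336,
                              seed = 1L,
                              growth_schedule = c("g2", "g1"),
                              arrest_growth = c("continue", "freeze"),
                              inhibition_scope = c("current", "r_max"),
                              arrest_mode = c("clock", "gate"),
                              division_axis = c("polar", "area"),
                              relax_tol_factor = 0.05,
                              max_substeps = 200L) {
  growth_schedule <- match.arg(growth_schedule)
  arrest_growth <- match.arg(arrest_growth)
  inhibition_scope <- match.arg(inhibition_scope)
  arrest_mode <- match.arg(arrest_mode)
  division_axis <- match.arg(division_axis)

  chk_num <- function(x, field, lower = NULL, upper = NULL,
                      allow_inf = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (!allow_inf && !is.finite(x))) {
      stop(sprintf("invalid value for '%s'", field), call. = FALSE)
    }
    if (!is.null(lower) && x < lower) {
      stop(sprintf("'%s' must be >= %g (got %g)", field, lower, x),
           call. = FALSE)
    }
    if (!is.null(upper) && x > upper) {
      stop(sprintf("'%s' must be <= %g (got %g)", field, upper, x),
           call. = FALSE)
    }
    x
  }
  chk_num(r_max, "r_max", lower = .Machine$double.eps)
  chk_num(a_div, "a_div", lower = .Machine$double.eps)
  chk_num(n_neigh, "n_neigh", lower = 0, allow_inf = TRUE)
  chk_num(f_rep, "f_rep", lower = .Machine$double.eps)
  chk_num(f_adh, "f_adh", lower = 0)
  chk_num(eta, "eta", lower = .Machine$double.eps)
  chk_num(dt, "dt", lower = .Machine$double.eps)
  chk_num(dt_mech, "dt_mech", lower = .Machine$double.eps)
  chk_num(noise_frac, "noise_frac", lower = 0, upper = 0.5)
  chk_num(birth_radius_factor, "birth_radius_factor", lower = 0.1, upper = 1)
  chk_num(daughter_offset_factor, "daughter_offset_factor",
          lower = .Machine$double.eps, upper = 2)
  chk_num(t_end, "t_end", lower = 0)
  chk_num(seed, "seed")
  chk_num(relax_tol_factor, "relax_tol_factor", lower = 1e-9)
  chk_num(max_substeps, "max_substeps", lower = 1)

  if (length(phase_fractions) != 4L || any(phase_fractions < 0)) {
    stop("'phase_fractions' must be four non-negative fractions",
         call. = FALSE)
  }
  if (abs(sum(phase_fractions) - 1) > 1e-12) {
    stop("'phase_fractions' must sum to 1", call. = FALSE)
  }
  names(phase_fractions) <- c("G1", "S", "G2", "M")
  if (dt_mech * f_rep / eta >= 1) {
    stop(paste0("'dt_mech' too large: dt_mech * f_rep / eta must be < 1 ",
                "so a pair cannot overshoot its spring equilibrium"),
         call. = FALSE)
  }

  p <- list(
    r_max = r_max, a_div = a_div, n_neigh = n_neigh,
    f_rep = f_rep, f_adh = f_adh, eta = eta,
    dt = dt, dt_mech = dt_mech, noise_frac = noise_frac,
    phase_fractions = phase_fractions,
    birth_radius_factor = birth_radius_factor,
    daughter_offset_factor = daughter_offset_factor,
    t_end = t_end, seed = as.integer(seed),
    growth_schedule = growth_schedule,
    arrest_growth = arrest_growth,
    inhibition_scope = inhibition_scope,
    arrest_mode = arrest_mode,
    division_axis = division_axis,
    relax_tol_factor = relax_tol_factor,
    max_substeps = as.integer(max_substeps),
    # derived
    adhesion_window = c(2 * r_max, 2.25 * r_max),
    inhibition_radius = 4 * r_max
  )
  class(p) <- "simulation_params"
  p
}

#' @export
print.simulation_params <- function(x, ...) {
  cat("Organoid simulation parameters\n")
  cat(sprintf("  r_max   %g um   a_div %g h   n_neigh %s cells\n",
              x$r_max, x$a_div, format(x$n_neigh)))
  cat(sprintf("  f_rep/eta %g /h   f_adh/eta %g /h   dt %g h (mech %g h)\n",
              x$f_rep / x$eta, x$f_adh / x$eta, x$dt, x$dt_mech))
  cat(sprintf("  noise_frac %g   t_end %g h   seed %d\n",
              x$noise_frac, x$t_end, x$seed))
  cat(sprintf("  growth '%s'   division axis '%s'\n",
              x$growth_schedule, x$division_axis))
  invisible(x)
}
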