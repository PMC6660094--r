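#' Replicated parameter sweep over (r_max, a_div, n_neigh)
#'
#' Runs `replicates` independent simulations for every parameter triple of
#' the grid, gates each run against the reference growth curve with
#' [accept_run()], and records the final morphometrics of completed runs.
#' A triple is accepted only if all of its replicates individually pass
#' both gate criteria.
#'
#' Runs whose diameter exceeds the upper band `mean + std` at an
#' observation day are truncated there (`early_stop = TRUE`): the band gate
#' is a conjunction over days, so such a run is already rejected and
#' simulating it further cannot change the verdict.  Truncated runs carry
#' `NA` morphometrics and `NA` R-squared.
#'
#' @param grid data frame with columns `r_max`, `a_div`, `n_neigh` (one row
#'   per triple), or a list of ranges passed to [expand.grid()].
#' @param curve a `growth_curve`.
#' @param replicates simulations per triple.
#' @param seed global seed; replicate seeds are derived from it.
#' @param base_params template [simulation_params()] supplying everything
#'   except the swept triple.
#' @param early_stop truncate runs that leave the band upward (see above).
#' @param asa_points Monte-Carlo points per cell for final-snapshot ASA.
#' @param keep_snapshots keep the final snapshot of every completed run
#'   (needed for [emit_morphochart()]).
#' @param progress print one line per triple.
#' @return object of class `organoid_sweep`: list with `runs` (one row per
#'   triple x replicate), `triples` (per-triple acceptance summary),
#'   `curve`, `seed`, and (optionally) `snapshots`.
#' @export
run_sweep <- function(grid, curve, replicates = 3, seed = 1,
                      base_params = simulation_params(),
                      early_stop = TRUE, asa_points = 500,
                      keep_snapshots = TRUE, progress = FALSE) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  need <- c("r_max", "a_div", "n_neigh")
  if (!all(need %in% names(grid))) {
    stop("grid must provide columns: ", paste(need, collapse = ", "))
  }
  stopifnot(replicates >= 1, nrow(grid) >= 1)

  runs <- list()
  snaps <- list()
  for (g in seq_len(nrow(grid))) {
    pars <- simulation_params(
      r_max = grid$r_max[g], a_div = grid$a_div[g],
      n_neigh = grid$n_neigh[g],
      f_rep = base_params$f_rep, f_adh = base_params$f_adh,
      eta = base_params$eta, dt = base_params$dt,
      dt_mech = base_params$dt_mech, noise_frac = base_params$noise_frac,
      phase_fractions = base_params$phase_fractions,
      birth_radius_factor = base_params$birth_radius_factor,
      daughter_offset_factor = base_params$daughter_offset_factor,
      t_end = base_params$t_end, seed = base_params$seed,
      growth_schedule = base_params$growth_schedule,
      division_axis = base_params$division_axis,
      relax_tol_factor = base_params$relax_tol_factor,
      max_substeps = base_params$max_substeps)
    out_times <- unique(sort(c(curve$day * 24, pars$t_end)))
    upper <- curve$mean_diameter_um + curve$std_um
    stop_fn <- if (early_stop) {
      function(snap) {
        k <- which(abs(curve$day * 24 - snap$time) < 1e-6)
        length(k) == 1 && organoid_diameter(snap) > upper[k] + 1e-9
      }
    } else {
      NULL
    }

    for (rep_i in seq_len(replicates)) {
      rep_seed <- derive_seed(seed, sprintf("sweep/%g/%g/%g/rep%d",
                                            grid$r_max[g], grid$a_div[g],
                                            grid$n_neigh[g], rep_i))
      row <- data.frame(
        r_max = grid$r_max[g], a_div = grid$a_div[g],
        n_neigh = grid$n_neigh[g], replicate = rep_i, seed = rep_seed,
        r2 = NA_real_, band_ok = FALSE, accepted_run = FALSE,
        truncated = FALSE, failed = FALSE,
        n_cells = NA_integer_, D_um = NA_real_, RGYR_um = NA_real_,
        ASA_um2 = NA_real_)
      traj <- tryCatch(
        run_simulation(pars, seed = rep_seed, output_times = out_times,
                       stop_fn = stop_fn),
        error = function(e) e)
      if (inherits(traj, "error")) {
        row$failed <- TRUE
        runs[[length(runs) + 1L]] <- row
        next
      }
      row$truncated <- traj$truncated
      if (!traj$truncated) {
        gate <- accept_run(traj, curve)
        row$r2 <- gate$r2
        row$band_ok <- all(gate$band_ok)
        row$accepted_run <- gate$accepted
        final <- traj$snapshots[[length(traj$snapshots)]]
        mm <- morphometrics(final, asa_points = asa_points,
                            seed = derive_seed(rep_seed, "asa"))
        row$n_cells <- mm$n_cells
        row$D_um <- mm$D_um
        row$RGYR_um <- mm$RGYR_um
        row$ASA_um2 <- mm$ASA_um2
        if (keep_snapshots) {
          snaps[[sprintf("%g_%g_%g_%d", row$r_max, row$a_div, row$n_neigh,
                         rep_i)]] <- final
        }
      }
      runs[[length(runs) + 1L]] <- row
    }
    if (progress) {
      message(sprintf("triple %d/%d (r_max=%g, a_div=%g, n_neigh=%g) done",
                      g, nrow(grid), grid$r_max[g], grid$a_div[g],
                      grid$n_neigh[g]))
    }
  }

  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs[, c("r_max", "a_div",
                                                    "n_neigh")],
                                     drop = TRUE), function(d) {
    data.frame(r_max = d$r_max[1], a_div = d$a_div[1],
               n_neigh = d$n_neigh[1],
               accepted = all(d$accepted_run),
               mean_r2 = if (all(!is.na(d$r2))) mean(d$r2) else NA_real_,
               mean_n_cells = mean(d$n_cells),
               mean_D_um = mean(d$D_um),
               mean_RGYR_um = mean(d$RGYR_um),
               mean_ASA_um2 = mean(d$ASA_um2))
  }))
  rownames(agg) <- NULL
  structure(list(runs = runs, triples = agg, curve = curve, seed = seed,
                 snapshots = if (keep_snapshots) snaps else NULL),
            class = "organoid_sweep")
}

#' @export
print.organoid_sweep <- function(x, ...) {
  cat(sprintf("Organoid sweep: %d triples x %d replicates, %d accepted\n",
              nrow(x$triples), max(x$runs$replicate), sum(x$triples$accepted)))
  invisible(x)
}

#' Heatmap table of a sweep at fixed cell radius
#'
#' For one value of `r_max`, builds the `(a_div x n_neigh)` table of the
#' replicate-mean value of a chosen quantity for accepted triples; entries
#' for rejected or missing triples are `NA` (blank).  The number of accepted
#' triples at this radius is attached as attribute `n_accepted`.
#'
#' @param sweep an `organoid_sweep`.
#' @param r_max the cell radius slice.
#' @param value one of `"r2"`, `"n_cells"`, `"D"`, `"RGYR"`, `"ASA"`.
#' @return matrix with `a_div` rows and `n_neigh` columns.
#' @export
emit_heatmap <- function(sweep, r_max,
                         value = c("r2", "n_cells", "D", "RGYR", "ASA")) {
  value <- match.arg(value)
  col <- switch(value, r2 = "mean_r2", n_cells = "mean_n_cells",
                D = "mean_D_um", RGYR = "mean_RGYR_um", ASA = "mean_ASA_um2")
  tr <- sweep$triples[sweep$triples$r_max == r_max, , drop = FALSE]
  a_levels <- sort(unique(tr$a_div))
  n_levels <- sort(unique(tr$n_neigh))
  m <- matrix(NA_real_, length(a_levels), length(n_levels),
              dimnames = list(a_div = a_levels, n_neigh = n_levels))
  acc <- tr[tr$accepted, , drop = FALSE]
  for (k in seq_len(nrow(acc))) {
    m[as.character(acc$a_div[k]), as.character(acc$n_neigh[k])] <- acc[[col]][k]
  }
  attr(m, "n_accepted") <- nrow(acc)
  m
}

#' Morphochart: representative final morphologies arranged by (a_div, n_neigh)
#'
#' For every accepted triple at the given radius, writes the final snapshot
#' of the representative replicate (the one with the median R-squared) and
#' its xy-projection silhouette (a point table of projected centers and
#' radii mimicking a bright-field outline) into `outdir`, plus an index CSV
#' listing exactly the accepted triples.  Rejected triples simply have no
#' entry (an empty slot in the chart).
#'
#' @param sweep an `organoid_sweep` run with `keep_snapshots = TRUE`.
#' @param r_max the cell radius slice.
#' @param outdir output directory (created if needed).
#' @return invisibly, the index data frame.
#' @export
emit_morphochart <- function(sweep, r_max, outdir) {
  if (is.null(sweep$snapshots)) {
    stop("sweep was run with keep_snapshots = FALSE")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tr <- sweep$triples[sweep$triples$r_max == r_max & sweep$triples$accepted, ,
                      drop = FALSE]
  index <- list()
  for (k in seq_len(nrow(tr))) {
    sub <- sweep$runs[sweep$runs$r_max == r_max &
                        sweep$runs$a_div == tr$a_div[k] &
                        sweep$runs$n_neigh == tr$n_neigh[k], , drop = FALSE]
    # representative replicate: median R^2 (middle of the sorted replicates)
    ord <- order(sub$r2)
    rep_i <- sub$replicate[ord[ceiling(length(ord) / 2)]]
    key <- sprintf("%g_%g_%g_%d", r_max, tr$a_div[k], tr$n_neigh[k], rep_i)
    snap <- sweep$snapshots[[key]]
    if (is.null(snap)) next
    snap_file <- file.path(outdir, paste0("snapshot_", key, ".csv"))
    write_snapshot(snap, snap_file, format = "csv")
    sil <- snap$cells[, c("x", "y", "radius")]
    sil_file <- file.path(outdir, paste0("silhouette_", key, ".csv"))
    write.csv(sil, sil_file, row.names = FALSE)
    index[[length(index) + 1L]] <- data.frame(
      r_max = r_max, a_div = tr$a_div[k], n_neigh = tr$n_neigh[k],
      replicate = rep_i, snapshot = basename(snap_file),
      silhouette = basename(sil_file))
  }
  index <- if (length(index) > 0) {
    do.call(rbind, index)
  } else {
    data.frame(r_max = numeric(0), a_div = numeric(0),
               n_neigh = numeric(0), replicate = integer(0),
               snapshot = character(0), silhouette = character(0))
  }
  write.csv(index, file.path(outdir, "index.csv"), row.names = FALSE)
  invisible(index)
}
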