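# exact Feret diameter of a union of 2D disks: max over disk pairs of
# center distance + both radii, floored at the largest single diameter.
# A two-sweep lower bound plus the triangle-inequality prune
#   d_ij + r_i + r_j <= s_i + s_j,   s_i = |p_i - c| + r_i
# keeps the candidate set to a thin outer shell, so the pair scan is exact
# without evaluating all N^2 pairs.
feret_disks <- function(p, r) {
  n <- nrow(p)
  if (n == 1) return(2 * r[1])
  ctr <- colMeans(p)
  s <- sqrt((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2) + r
  i1 <- which.max(s)
  d1 <- sqrt((p[, 1] - p[i1, 1])^2 + (p[, 2] - p[i1, 2])^2) + r + r[i1]
  j1 <- which.max(d1)
  d2 <- sqrt((p[, 1] - p[j1, 1])^2 + (p[, 2] - p[j1, 2])^2) + r + r[j1]
  f_low <- max(d1[j1], max(d2), 2 * max(r))
  keep <- which(s >= f_low - max(s))
  if (length(keep) >= 2) {
    q <- p[keep, , drop = FALSE]
    dmat <- as.matrix(dist(q)) + outer(r[keep], r[keep], "+")
    f_low <- max(f_low, dmat[upper.tri(dmat)])
  }
  f_low
}

#' Projected (Feret) diameter of an organoid on a coordinate plane
#'
#' The maximal caliper extent of the union of the projected cell disks:
#' the maximum over cell pairs of the projected center distance plus both
#' radii, floored at the largest single-cell diameter.
#'
#' @param snapshot an `organoid_snapshot`.
#' @param plane one of `"xy"`, `"yz"`, `"xz"`.
#' @return diameter in micrometers.
#' @export
#' @examples
#' projection_diameter(make_fixture("single", r = 7), "xy")  # 14
projection_diameter <- function(snapshot, plane = c("xy", "yz", "xz")) {
  plane <- match.arg(plane)
  cols <- switch(plane, xy = c("x", "y"), yz = c("y", "z"),
                 xz = c("x", "z"))
  p <- as.matrix(snapshot$cells[, cols])
  feret_disks(p, snapshot$cells$radius)
}

#' Organoid diameter averaged over the three coordinate-plane projections
#'
#' Arithmetic mean of the xy, yz and xz projection diameters; the scalar
#' size measure used for growth-curve gating.
#'
#' @param snapshot an `organoid_snapshot`.
#' @return diameter in micrometers.
#' @export
organoid_diameter <- function(snapshot) {
  mean(c(projection_diameter(snapshot, "xy"),
         projection_diameter(snapshot, "yz"),
         projection_diameter(snapshot, "xz")))
}

#' Radius of gyration of an organoid
#'
#' Root-mean-square distance of the cell centers from the organoid center
#' of mass (the unweighted mean of centers):
#' `RGYR = sqrt( sum_i |X_i - X_C|^2 / N_cells )`.  The square root is taken
#' so the value carries units of micrometers.  Lower values indicate a more
#' compact organoid.
#'
#' @param snapshot an `organoid_snapshot`.
#' @return radius of gyration in micrometers.
#' @export
#' @examples
#' radius_of_gyration(make_fixture("cube", half_edge = 10))  # 10 * sqrt(3)
radius_of_gyration <- function(snapshot) {
  pos <- cell_positions(snapshot)
  ctr <- colMeans(pos)
  sqrt(mean((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2 +
              (pos[, 3] - ctr[3])^2))
}

#' Monte-Carlo accessible surface area of an organoid
#'
#' For every cell, `n_points` test points are placed on a sphere of radius
#' `radius * (1 + epsilon)` around its center using area-uniform direction
#' sampling, so each point stands for an equal `1/n_points` fraction of the
#' cell's surface `4 pi R^2`.  A point is discarded if it lies inside any
#' other (equally inflated) cell; the surviving points' area fractions are
#' summed over all cells.  Buried cells therefore contribute nothing, and an
#' isolated cell contributes exactly `4 pi R^2`.
#'
#' Directions for each cell are drawn from a private stream derived from
#' `(seed, cell id)`, so the estimate does not depend on cell ordering.
#'
#' @param snapshot an `organoid_snapshot`.
#' @param n_points Monte-Carlo points per cell (default 500).
#' @param seed seed for the direction sampling.
#' @param epsilon relative inflation of the sampling shell and of the
#'   removal test (both sides use the same inflation); the default makes the
#'   test a geometric contact test.
#' @param per_cell return the vector of per-cell contributions (in snapshot
#'   row order) instead of the total.
#' @return accessible surface area in square micrometers (scalar, or a
#'   per-cell vector when `per_cell = TRUE`).
#' @export
#' @examples
#' asa <- accessible_surface_area(make_fixture("single", r = 7))
#' all.equal(asa, 4 * pi * 7^2)
accessible_surface_area <- function(snapshot, n_points = 500, seed = 1,
                                    epsilon = 1e-6, per_cell = FALSE) {
  stopifnot(n_points >= 1)
  cells <- snapshot$cells
  n <- nrow(cells)
  pos <- cell_positions(snapshot)
  rad <- cells$radius
  rad_inf <- rad * (1 + epsilon)

  # candidate blockers: cells whose inflated spheres can contain another
  # cell's sampling shell points
  nb <- vector("list", n)
  if (n > 1) {
    prs <- .osim_pairs_within(pos, 2 * max(rad_inf))
    if (nrow(prs) > 0) {
      for (k in seq_len(nrow(prs))) {
        i <- prs[k, 1]; j <- prs[k, 2]
        d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        if (d < rad_inf[i] + rad_inf[j]) {
          nb[[i]] <- c(nb[[i]], j)
          nb[[j]] <- c(nb[[j]], i)
        }
      }
    }
  }

  contrib <- numeric(n)
  for (i in seq_len(n)) {
    area_i <- 4 * pi * rad[i]^2
    blockers <- nb[[i]]
    if (is.null(blockers)) {
      contrib[i] <- area_i
      next
    }
    pts <- with_seed(as.integer((abs(seed) + cells$id[i] * 1000003) %%
                                  2147483647), {
      z <- runif(n_points, -1, 1)
      phi <- runif(n_points, 0, 2 * pi)
      s <- sqrt(pmax(0, 1 - z^2))
      cbind(pos[i, 1] + rad_inf[i] * s * cos(phi),
            pos[i, 2] + rad_inf[i] * s * sin(phi),
            pos[i, 3] + rad_inf[i] * z)
    })
    alive <- rep(TRUE, n_points)
    for (j in blockers) {
      if (!any(alive)) break
      d2 <- (pts[, 1] - pos[j, 1])^2 + (pts[, 2] - pos[j, 2])^2 +
        (pts[, 3] - pos[j, 3])^2
      alive <- alive & d2 >= rad_inf[j]^2
    }
    contrib[i] <- area_i * sum(alive) / n_points
  }
  if (per_cell) contrib else sum(contrib)
}

#' Morphometric record of one organoid snapshot
#'
#' Computes the three structural scores (projection-averaged diameter,
#' radius of gyration, accessible surface area) plus the cell count.
#'
#' @param snapshot an `organoid_snapshot`.
#' @param asa_points Monte-Carlo points per cell for the ASA estimate.
#' @param seed seed for ASA sampling.
#' @return one-row data frame: `time_h`, `n_cells`, `D_um`, `RGYR_um`,
#'   `ASA_um2`, `ASA_1e4_um2` (the conventional reporting scale).
#' @export
morphometrics <- function(snapshot, asa_points = 500, seed = 1) {
  asa <- accessible_surface_area(snapshot, n_points = asa_points,
                                 seed = seed)
  data.frame(
    time_h = snapshot$time,
    n_cells = n_cells(snapshot),
    D_um = organoid_diameter(snapshot),
    RGYR_um = radius_of_gyration(snapshot),
    ASA_um2 = asa,
    ASA_1e4_um2 = asa / 1e4
  )
}
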