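#' Deterministic geometric fixtures for tests and benchmarks
#'
#' Constructs small organoid snapshots with known closed-form morphometrics:
#' \describe{
#'   \item{single}{one cell of radius `r` at the origin.}
#'   \item{pair}{two cells of radius `r` with surface gap `gap` (touching
#'     at `gap = 0`, centers `2 r + gap` apart) along x.}
#'   \item{chain}{`n` cells in a straight line along x, centers spaced
#'     `spacing` apart (default touching, `2 r`).}
#'   \item{cube}{8 cells at the corners of a cube of half-edge `half_edge`
#'     (radius of gyration is `half_edge * sqrt(3)`).}
#'   \item{fcc_ball}{all sites of a face-centered-cubic packing with
#'     nearest-neighbor distance `2 r` within `ball_radius` of the origin.}
#'   \item{shell}{a buried-cell fixture: one central cell plus 12 neighbors
#'     along the FCC kissing directions at center distance
#'     `2 * shell_factor * r`.  The default `shell_factor = 0.65` overlaps
#'     the neighbors with the central cell so that every direction of its
#'     sampling sphere falls inside some neighbor (removal cap half-angle
#'     `acos(shell_factor)` exceeds the 45-degree covering radius of the
#'     kissing directions) and the central cell is fully buried.  Exactly
#'     touching neighbors (`shell_factor = 1`) would remove nothing under
#'     the geometric contact test.}
#' }
#'
#' @param name fixture name.
#' @param r cell radius, micrometers.
#' @param gap surface gap for `"pair"`.
#' @param n chain length for `"chain"`.
#' @param spacing center spacing for `"chain"` (default `2 r`).
#' @param half_edge cube half-edge for `"cube"`.
#' @param ball_radius ball radius for `"fcc_ball"`.
#' @param shell_factor neighbor distance for `"shell"`, as a fraction of the
#'   touching distance `2 r`.
#' @return an `organoid_snapshot` at time 0.
#' @export
#' @examples
#' radius_of_gyration(make_fixture("cube", half_edge = 5))  # 5 * sqrt(3)
make_fixture <- function(name = c("single", "pair", "chain", "cube",
                                  "fcc_ball", "shell"),
                         r = 7, gap = 0, n = 5, spacing = NULL,
                         half_edge = 10, ball_radius = 30,
                         shell_factor = 0.65) {
  name <- match.arg(name)
  pos <- switch(
    name,
    single = matrix(0, 1, 3),
    pair = rbind(c(0, 0, 0), c(2 * r + gap, 0, 0)),
    chain = {
      if (is.null(spacing)) spacing <- 2 * r
      cbind((seq_len(n) - 1) * spacing, 0, 0)
    },
    cube = half_edge * as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    fcc_ball = fcc_sites(ball_radius, 2 * r),
    shell = rbind(c(0, 0, 0),
                  fcc_kissing_directions() * 2 * r * shell_factor))
  cells <- data.frame(id = seq_len(nrow(pos)),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      radius = r)
  organoid_snapshot(cells, time = 0)
}

# the 12 nearest-neighbor directions of an FCC lattice (cuboctahedron
# vertices), unit length
fcc_kissing_directions <- function() {
  v <- rbind(
    c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
    c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
    c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  v / sqrt(2)
}

# FCC lattice sites with nearest-neighbor distance `nn` inside a ball
fcc_sites <- function(ball_radius, nn) {
  a <- nn * sqrt(2)  # conventional cubic lattice constant
  m <- ceiling(ball_radius / a) + 1
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  base <- cbind(g$i, g$j, g$k)
  offsets <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                   c(0, 0.5, 0.5))
  pts <- do.call(rbind, lapply(seq_len(4), function(o) {
    sweep(base, 2, offsets[o, ], "+")
  })) * a
  pts[sqrt(rowSums(pts^2)) <= ball_radius + 1e-9, , drop = FALSE]
}
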