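#' Organoid snapshot: the cell population at one time point
#'
#' A snapshot is a data frame of per-cell state plus the simulated time.
#' Required columns: `id` (integer), `x`, `y`, `z` (micrometers), `radius`
#' (micrometers), `phase` (one of G1, S, G2, M), `age`, `div_age` (hours),
#' `arrested` (logical) and `n_neighbors` (integer).  Rows are kept ordered
#' by `id`.
#'
#' @param cells data frame of per-cell state; missing bookkeeping columns
#'   (`phase`, `age`, `div_age`, `arrested`, `n_neighbors`) are filled with
#'   defaults so that morphometrics can run on bare `(id, x, y, z, radius)`
#'   tables.
#' @param time simulated time in hours.
#' @return an object of class `organoid_snapshot`.
#' @export
#' @examples
#' snap <- organoid_snapshot(data.frame(id = 1, x = 0, y = 0, z = 0, radius = 7))
#' n_cells(snap)
organoid_snapshot <- function(cells, time = 0) {
  stopifnot(is.data.frame(cells))
  required <- c("id", "x", "y", "z", "radius")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop("snapshot is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(cells) == 0) {
    stop("snapshot must contain at least one cell", call. = FALSE)
  }
  if (anyDuplicated(cells$id)) stop("duplicate cell ids", call. = FALSE)
  if (any(!is.finite(as.matrix(cells[, c("x", "y", "z", "radius")])))) {
    stop("non-finite cell coordinates or radii", call. = FALSE)
  }
  if (any(cells$radius <= 0)) stop("cell radii must be positive", call. = FALSE)
  if (is.null(cells$phase)) cells$phase <- "G1"
  if (is.null(cells$age)) cells$age <- 0
  if (is.null(cells$div_age)) cells$div_age <- NA_real_
  if (is.null(cells$arrested)) cells$arrested <- FALSE
  if (is.null(cells$n_neighbors)) cells$n_neighbors <- NA_integer_
  cells$id <- as.integer(cells$id)
  cells <- cells[order(cells$id),
                 c("id", "x", "y", "z", "radius", "phase", "age",
                   "div_age", "arrested", "n_neighbors")]
  rownames(cells) <- NULL
  structure(list(time = time, cells = cells), class = "organoid_snapshot")
}

#' @export
print.organoid_snapshot <- function(x, ...) {
  cat(sprintf("Organoid snapshot: %d cells at t = %g h\n",
              n_cells(x), x$time))
  invisible(x)
}

#' Number of cells in a snapshot
#' @param snapshot an `organoid_snapshot`.
#' @return integer cell count.
#' @export
n_cells <- function(snapshot) nrow(snapshot$cells)

#' Center of mass of an organoid
#'
#' The unweighted mean of the cell centers (cells are near-uniform in size,
#' so no mass weighting is applied).
#'
#' @param snapshot an `organoid_snapshot`.
#' @return numeric 3-vector `(x, y, z)` in micrometers.
#' @export
center_of_mass <- function(snapshot) {
  colMeans(as.matrix(snapshot$cells[, c("x", "y", "z")]))
}

# internal: positions as an N x 3 matrix
cell_positions <- function(snapshot) {
  as.matrix(snapshot$cells[, c("x", "y", "z")])
}
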