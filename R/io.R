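# keys of the simulation section, in canonical order; these mirror the
# arguments of simulation_params() exactly
sim_config_keys <- function() {
  c("r_max", "a_div", "n_neigh", "f_rep", "f_adh", "eta", "dt", "dt_mech",
    "noise_frac", "phase_fractions", "birth_radius_factor",
    "daughter_offset_factor", "t_end", "seed", "growth_schedule",
    "arrest_mode", "arrest_growth", "inhibition_scope", "division_axis",
    "relax_tol_factor", "max_substeps")
}

#' Read / write a run configuration file
#'
#' The configuration is a human-readable YAML file with a `simulation`
#' section mirroring [simulation_params()] key for key, and optional
#' `sweep` (grid ranges, `replicates`) and `classify` (`k`, `n_restarts`,
#' `scale_features`) sections.  Unknown keys are rejected with the
#' offending key named; omitted keys fall back to the documented defaults.
#' Writing then reading a configuration reproduces the same parameters.
#'
#' @param path file path.
#' @return `read_config()` returns a list with elements `params` (a
#'   `simulation_params`), `sweep` and `classify` (lists, possibly empty),
#'   and `defaults_used` (names of simulation keys filled from defaults).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("simulation", "sweep", "classify"))
  if (length(unknown) > 0) {
    stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
  }
  sim <- raw$simulation
  if (is.null(sim)) sim <- list()
  unknown <- setdiff(names(sim), sim_config_keys())
  if (length(unknown) > 0) {
    stop("unknown simulation key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(sim$phase_fractions)) {
    sim$phase_fractions <- unlist(sim$phase_fractions)
  }
  defaults_used <- setdiff(sim_config_keys(), names(sim))
  params <- do.call(simulation_params, sim)

  swp <- raw$sweep
  if (is.null(swp)) swp <- list()
  unknown <- setdiff(names(swp), c("r_max", "a_div", "n_neigh", "replicates",
                                   "early_stop", "asa_points"))
  if (length(unknown) > 0) {
    stop("unknown sweep key(s): ", paste(unknown, collapse = ", "))
  }
  cls <- raw$classify
  if (is.null(cls)) cls <- list()
  unknown <- setdiff(names(cls), c("k", "n_restarts", "scale_features"))
  if (length(unknown) > 0) {
    stop("unknown classify key(s): ", paste(unknown, collapse = ", "))
  }
  list(params = params, sweep = swp, classify = cls,
       defaults_used = defaults_used)
}

#' @param params a [simulation_params()] object.
#' @param sweep,classify optional setting lists to embed.
#' @rdname read_config
#' @export
write_config <- function(params, path, sweep = NULL, classify = NULL) {
  sim <- params[sim_config_keys()]
  sim$phase_fractions <- as.list(sim$phase_fractions)
  out <- list(simulation = sim)
  if (!is.null(sweep)) out$sweep <- sweep
  if (!is.null(classify)) out$classify <- classify
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write / read an organoid snapshot
#'
#' Two on-disk dialects carry the same ten per-cell fields
#' (`id, x, y, z, radius, phase, age, div_age, arrested, n_neighbors`;
#' positions and radii in micrometers, ages in hours):
#' \describe{
#'   \item{csv}{a plain CSV with header.}
#'   \item{xyz}{an extended-XYZ file: first line the cell count, second
#'     line a comment carrying `Time=<hours>` and the column layout, then
#'     one whitespace-separated record per cell.}
#' }
#' Numeric fields are written with full double precision, so a write/read
#' round trip reproduces the snapshot exactly.  Cells are stored ordered by
#' id.
#'
#' @param snapshot an `organoid_snapshot`.
#' @param path file path.
#' @param format `"csv"` or `"xyz"`; `read_snapshot()` autodetects by
#'   content when `format = NULL`.
#' @return `read_snapshot()` returns an `organoid_snapshot`.
#' @export
write_snapshot <- function(snapshot, path, format = c("csv", "xyz")) {
  format <- match.arg(format)
  cells <- snapshot$cells
  num <- function(x) sprintf("%.17g", x)
  if (format == "csv") {
    lines <- c(
      "id,x,y,z,radius,phase,age,div_age,arrested,n_neighbors",
      sprintf("%d,%s,%s,%s,%s,%s,%s,%s,%s,%s",
              cells$id, num(cells$x), num(cells$y), num(cells$z),
              num(cells$radius), cells$phase, num(cells$age),
              ifelse(is.na(cells$div_age), "NA", num(cells$div_age)),
              ifelse(cells$arrested, "TRUE", "FALSE"),
              ifelse(is.na(cells$n_neighbors), "NA",
                     as.character(cells$n_neighbors))))
    writeLines(c(sprintf("# time_h=%s", num(snapshot$time)), lines), path)
  } else {
    header <- sprintf(paste0(
      "Time=%s Properties=id:I:1:pos:R:3:radius:R:1:phase:S:1:age:R:1:",
      "div_age:R:1:arrested:I:1:n_neighbors:I:1"), num(snapshot$time))
    rows <- sprintf("%d %s %s %s %s %s %s %s %d %s",
                    cells$id, num(cells$x), num(cells$y), num(cells$z),
                    num(cells$radius), cells$phase, num(cells$age),
                    ifelse(is.na(cells$div_age), "NA", num(cells$div_age)),
                    as.integer(cells$arrested),
                    ifelse(is.na(cells$n_neighbors), "NA",
                           as.character(cells$n_neighbors)))
    writeLines(c(as.character(nrow(cells)), header, rows), path)
  }
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path, format = NULL) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty snapshot file: ", path)
  if (is.null(format)) {
    format <- if (grepl("^[0-9]+$", trimws(lines[1]))) "xyz" else "csv"
  }
  parse_num <- function(x, line_no, field) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & x != "NA")
    if (length(bad) > 0) {
      stop(sprintf("malformed %s value at line %d of %s", field,
                   line_no[bad[1]], path))
    }
    out
  }
  if (format == "csv") {
    time_h <- 0
    if (startsWith(lines[1], "#")) {
      m <- regmatches(lines[1], regexec("time_h=([-0-9.eE+]+)", lines[1]))[[1]]
      if (length(m) == 2) time_h <- as.numeric(m[2])
      lines <- lines[-1]
    }
    if (length(lines) < 1) stop("snapshot file has no header: ", path)
    header <- strsplit(lines[1], ",")[[1]]
    body <- lines[-1]
    body <- body[nzchar(trimws(body))]
    if (length(body) == 0) {
      stop("snapshot file contains a header but no cells: ", path)
    }
    parts <- strsplit(body, ",")
    lens <- lengths(parts)
    if (any(lens != length(header))) {
      stop(sprintf("malformed row at line %d of %s",
                   which(lens != length(header))[1] + 2L, path))
    }
    tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(tab) <- header
    line_no <- seq_along(body) + 2L
  } else {
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("malformed extended-XYZ count at line 1 of ", path)
    if (n == 0 || length(lines) < 2 + n) {
      stop("snapshot file truncated or empty: ", path)
    }
    time_h <- 0
    m <- regmatches(lines[2], regexec("Time=([-0-9.eE+]+)", lines[2]))[[1]]
    if (length(m) == 2) time_h <- as.numeric(m[2])
    body <- lines[3:(2 + n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    lens <- lengths(parts)
    if (any(lens != 10L)) {
      stop(sprintf("malformed row at line %d of %s",
                   which(lens != 10L)[1] + 2L, path))
    }
    tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(tab) <- c("id", "x", "y", "z", "radius", "phase", "age",
                    "div_age", "arrested", "n_neighbors")
    line_no <- seq_along(body) + 2L
  }
  need <- c("id", "x", "y", "z", "radius")
  if (!all(need %in% names(tab))) {
    stop("snapshot file must provide columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  cells <- data.frame(
    id = as.integer(parse_num(tab$id, line_no, "id")),
    x = parse_num(tab$x, line_no, "x"),
    y = parse_num(tab$y, line_no, "y"),
    z = parse_num(tab$z, line_no, "z"),
    radius = parse_num(tab$radius, line_no, "radius"))
  if (!is.null(tab$phase)) cells$phase <- tab$phase
  if (!is.null(tab$age)) cells$age <- parse_num(tab$age, line_no, "age")
  if (!is.null(tab$div_age)) {
    cells$div_age <- parse_num(tab$div_age, line_no, "div_age")
  }
  if (!is.null(tab$arrested)) {
    cells$arrested <- tab$arrested %in% c("TRUE", "1")
  }
  if (!is.null(tab$n_neighbors)) {
    cells$n_neighbors <- as.integer(parse_num(tab$n_neighbors, line_no,
                                              "n_neighbors"))
  }
  organoid_snapshot(cells, time = time_h)
}

#' Write the trajectory summary CSV
#'
#' One row per emitted snapshot: `time_h, n_cells, D_um, RGYR_um, ASA_um2,
#' ASA_1e4_um2`.
#'
#' @param trajectory an `organoid_trajectory`.
#' @param path file path.
#' @param asa_points,seed passed to [trajectory_summary()].
#' @return invisibly, the summary data frame.
#' @export
write_trajectory_summary <- function(trajectory, path, asa_points = 500,
                                     seed = trajectory$seed) {
  s <- trajectory_summary(trajectory, asa_points = asa_points, seed = seed)
  write.csv(s, path, row.names = FALSE)
  invisible(s)
}

# tiny polynomial rolling hash, for manifest config fingerprints
config_fingerprint <- function(x) {
  h <- 5381
  for (ch in utf8ToInt(paste(x, collapse = "\n"))) {
    h <- (h * 33 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Run manifest: reproducibility record of a pipeline stage
#'
#' Lists the configuration fingerprint, seed, package version, stage name
#' and every output file a stage wrote, so deterministic stages can be
#' re-run and compared bit for bit.
#'
#' @param stage stage name (`"simulate"`, `"sweep"`, ...).
#' @param params the `simulation_params` used (hashed into the manifest).
#' @param seed the global seed.
#' @param outputs character vector of output file paths.
#' @param path where to write the manifest JSON; `NULL` to skip writing.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(stage, params, seed, outputs, path = NULL) {
  man <- list(
    stage = stage,
    config_hash = config_fingerprint(yaml::as.yaml(params[sim_config_keys()])),
    seed = seed,
    package_version = as.character(utils::packageVersion("organoidsim")),
    outputs = as.character(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(man))
  }
  man
}
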