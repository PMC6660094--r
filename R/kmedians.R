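# L1 (Manhattan) distances from every point to every centroid
l1_dist <- function(points, centroids) {
  d <- matrix(0, nrow(points), nrow(centroids))
  for (k in seq_len(nrow(centroids))) {
    d[, k] <- abs(points[, 1] - centroids[k, 1]) +
      abs(points[, 2] - centroids[k, 2])
  }
  d
}

# assign points to the L1-nearest centroid; ties go to the lower index
# (max.col with "first" on the negated distances)
l1_assign <- function(points, centroids) {
  max.col(-l1_dist(points, centroids), ties.method = "first")
}

kmedians_cost <- function(points, centroids, assign) {
  sum(abs(points - centroids[assign, , drop = FALSE]))
}

# one Lloyd-style run; `centers` are the row indices of the initial
# centroids (farthest-point from a seeded start, or a random subset)
kmedians_once <- function(points, k, centers, max_iter = 100) {
  centroids <- points[centers, , drop = FALSE]
  assign <- l1_assign(points, centroids)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) == 0) {
        # empty cluster: reseed at the point farthest from its own centroid
        resid <- abs(points[, 1] - centroids[assign, 1]) +
          abs(points[, 2] - centroids[assign, 2])
        far <- which.max(resid)
        centroids[j, ] <- points[far, ]
      } else {
        centroids[j, 1] <- median(points[members, 1])
        centroids[j, 2] <- median(points[members, 2])
      }
    }
    new_assign <- l1_assign(points, centroids)
    if (all(new_assign == assign)) break
    assign <- new_assign
  }
  list(centroids = centroids, assign = assign,
       cost = kmedians_cost(points, centroids, assign))
}

#' Fit a k-medians morphophenotype model on (RGYR, ASA) features
#'
#' Classical k-medians: Lloyd-style alternation of L1 (Manhattan) nearest
#' assignment and componentwise-median centroid updates, restarted
#' `n_restarts` times from seeded farthest-point initializations; the run
#' with the lowest total L1 cost wins.  Features are the radius of gyration
#' in micrometers and the accessible surface area in units of 1e4 square
#' micrometers, whose dynamic ranges are comparable, so no scaling is
#' applied by default.
#'
#' Clusters are labeled in order of descending centroid RGYR: Spherical
#' (large, loose), Compact, Elongated, Branched (small RGYR and ASA).
#' Input rows are sorted internally before initialization, so the fit is
#' invariant under permutations of the input.
#'
#' @param points matrix or data frame with two columns: RGYR (um) and
#'   ASA (1e4 um^2).  See [morphometric_features()].
#' @param k number of classes (default 4).
#' @param n_restarts independent restarts.
#' @param seed RNG seed for the restart initializations.
#' @param scale_features divide each feature by its median absolute
#'   deviation before clustering (off by default).
#' @return object of class `morphophenotype_model`: list with `centroids`
#'   (k x 2, ordered by descending RGYR), `labels`, `cost`, `k`,
#'   `assignments` (for the training points, in input order).
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(40, 100), 20), matrix(rnorm(40, 70), 20))
#' fit_kmedians(pts, k = 2)
fit_kmedians <- function(points, k = 4, n_restarts = 20, seed = 1,
                         scale_features = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have exactly two columns")
  storage.mode(points) <- "double"
  if (anyNA(points)) stop("points contain missing values")
  n_distinct <- nrow(unique(points))
  if (n_distinct < k) {
    stop(sprintf("need at least k = %d distinct points (got %d)",
                 k, n_distinct))
  }
  scales <- c(1, 1)
  if (scale_features) {
    scales <- apply(points, 2, stats::mad)
    scales[scales == 0] <- 1
    points <- sweep(points, 2, scales, "/")
  }
  # canonical order so the restart schedule is permutation-invariant
  ord <- order(points[, 1], points[, 2])
  pts <- points[ord, , drop = FALSE]

  farthest_init <- function(first) {
    centers <- integer(k)
    centers[1] <- first
    if (k > 1) {
      dmin <- abs(pts[, 1] - pts[first, 1]) + abs(pts[, 2] - pts[first, 2])
      for (j in 2:k) {
        centers[j] <- which.max(dmin)
        dj <- abs(pts[, 1] - pts[centers[j], 1]) +
          abs(pts[, 2] - pts[centers[j], 2])
        dmin <- pmin(dmin, dj)
      }
    }
    centers
  }
  best <- NULL
  with_seed(derive_seed(seed, "kmedians"), {
    for (r in seq_len(n_restarts)) {
      # alternate a farthest-point start with random k-subsets for diversity
      centers <- if (r %% 2 == 1) {
        farthest_init(sample.int(nrow(pts), 1))
      } else {
        sample.int(nrow(pts), k)
      }
      fit <- kmedians_once(pts, k, centers)
      if (is.null(best) || fit$cost < best$cost - 1e-12) best <- fit
    }
  })

  # order classes by descending RGYR centroid
  cl_order <- order(best$centroids[, 1], decreasing = TRUE)
  centroids <- best$centroids[cl_order, , drop = FALSE] * rep(scales, each = k)
  relabel <- match(seq_len(k), cl_order)
  assign_sorted <- relabel[best$assign]
  assignments <- integer(nrow(points))
  assignments[ord] <- assign_sorted

  labels <- if (k == 4) {
    c("Spherical", "Compact", "Elongated", "Branched")
  } else {
    paste0("Class", seq_len(k))
  }
  colnames(centroids) <- c("RGYR_um", "ASA_1e4_um2")
  rownames(centroids) <- labels
  structure(list(k = k, centroids = centroids, labels = labels,
                 cost = best$cost, assignments = assignments,
                 scales = scales),
            class = "morphophenotype_model")
}

#' @export
print.morphophenotype_model <- function(x, ...) {
  cat(sprintf("k-medians morphophenotype model (k = %d, L1 cost %.4g)\n",
              x$k, x$cost))
  print(round(x$centroids, 2))
  invisible(x)
}

#' Assign organoids to morphophenotype classes
#'
#' Nearest-centroid (L1) assignment of new organoids; ties are broken
#' toward the lower class index (higher-RGYR class).
#'
#' @param x a morphometrics record (data frame with `RGYR_um` and
#'   `ASA_um2` or `ASA_1e4_um2` columns) or a two-column matrix of
#'   (RGYR um, ASA 1e4 um^2) features.
#' @param model a fitted `morphophenotype_model`.
#' @return factor of class labels, one per row of `x`.
#' @export
assign_class <- function(x, model) {
  pts <- morphometric_features(x)
  idx <- l1_assign(pts, model$centroids)
  factor(model$labels[idx], levels = model$labels)
}

#' Extract (RGYR, ASA) clustering features
#'
#' Normalizes the various inputs (morphometrics records, sweep results,
#' plain matrices) into the two-column feature matrix used for
#' classification: RGYR in micrometers, ASA in 1e4 square micrometers.
#'
#' @param x data frame with `RGYR_um` and `ASA_1e4_um2` (or `ASA_um2`)
#'   columns, or a two-column matrix already on the feature scale.
#' @return numeric matrix with columns `RGYR_um`, `ASA_1e4_um2`.
#' @export
morphometric_features <- function(x) {
  if (is.data.frame(x)) {
    if ("RGYR_um" %in% names(x)) {
      rg <- x$RGYR_um
    } else if ("mean_RGYR_um" %in% names(x)) {
      rg <- x$mean_RGYR_um
    } else {
      stop("no RGYR column found")
    }
    if ("ASA_1e4_um2" %in% names(x)) {
      asa <- x$ASA_1e4_um2
    } else if ("ASA_um2" %in% names(x)) {
      asa <- x$ASA_um2 / 1e4
    } else if ("mean_ASA_um2" %in% names(x)) {
      asa <- x$mean_ASA_um2 / 1e4
    } else {
      stop("no ASA column found")
    }
    cbind(RGYR_um = rg, ASA_1e4_um2 = asa)
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 2) stop("feature matrix must have two columns")
    colnames(m) <- c("RGYR_um", "ASA_1e4_um2")
    m
  }
}
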