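# brute-force k-medians optimum by enumerating all label assignments and
# taking componentwise medians per cluster (tiny n only)
brute_kmedians <- function(points, k) {
  n <- nrow(points)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (row in seq_len(nrow(grid))) {
    lab <- grid[row, ]
    cost <- 0
    for (j in seq_len(k)) {
      m <- points[lab == j, , drop = FALSE]
      if (nrow(m) == 0) next
      cost <- cost + sum(abs(m[, 1] - median(m[, 1]))) +
        sum(abs(m[, 2] - median(m[, 2])))
    }
    if (cost < best) best <- cost
  }
  best
}

test_that("k distinct points give a zero-cost model with one point per class", {
  pts <- cbind(c(110, 95, 83, 72), c(52, 37, 28, 20))
  m <- fit_kmedians(pts, k = 4, n_restarts = 5, seed = 1)
  expect_equal(m$cost, 0)
  expect_equal(unname(sort(m$centroids[, 1])), sort(pts[, 1]))
  # labels ordered by descending RGYR centroid
  expect_equal(m$labels, c("Spherical", "Compact", "Elongated", "Branched"))
  expect_equal(unname(m$centroids[, 1]), c(110, 95, 83, 72))
  expect_equal(as.character(assign_class(pts, m)),
               c("Spherical", "Compact", "Elongated", "Branched"))
})

test_that("the Lloyd fit matches the exhaustive optimum on tiny inputs", {
  for (seed in 1:4) {
    pts <- with_seed(seed, cbind(runif(8, 60, 130), runif(8, 15, 60)))
    fit <- fit_kmedians(pts, k = 3, n_restarts = 40, seed = seed)
    expect_equal(fit$cost, brute_kmedians(pts, 3), tolerance = 1e-9)
  }
})

test_that("four planted blobs are recovered within their spread", {
  centers <- rbind(c(100, 50), c(90, 36), c(80, 28), c(74, 21))
  pts <- with_seed(11, {
    do.call(rbind, lapply(1:4, function(j) {
      cbind(centers[j, 1] + runif(20, -1, 1),
            centers[j, 2] + runif(20, -1, 1))
    }))
  })
  m <- fit_kmedians(pts, k = 4, seed = 2)
  ord <- order(centers[, 1], decreasing = TRUE)
  expect_true(all(abs(m$centroids[, 1] - centers[ord, 1]) <= 1))
  expect_true(all(abs(m$centroids[, 2] - centers[ord, 2]) <= 1))
  # every point lands with its own blob
  truth <- rep(rank(-centers[, 1]), each = 20)
  expect_equal(as.integer(factor(m$assignments)), as.integer(truth))
})

test_that("the fit is invariant under permutations of the input rows", {
  pts <- with_seed(21, cbind(runif(40, 60, 130), runif(40, 15, 60)))
  m1 <- fit_kmedians(pts, seed = 5)
  perm <- with_seed(22, sample(nrow(pts)))
  m2 <- fit_kmedians(pts[perm, ], seed = 5)
  expect_equal(m1$centroids, m2$centroids)
  expect_equal(m1$cost, m2$cost)
  expect_equal(m1$assignments[perm], m2$assignments)
})

test_that("assignment uses L1 distance with ties to the lower class index", {
  model <- structure(list(
    k = 4,
    centroids = matrix(c(107.33, 92.86, 82.36, 73.70,
                         50.50, 36.42, 27.76, 21.38), ncol = 2,
                       dimnames = list(NULL, c("RGYR_um", "ASA_1e4_um2"))),
    labels = c("Spherical", "Compact", "Elongated", "Branched")),
    class = "morphophenotype_model")
  # a centroid maps to its own class
  expect_equal(as.character(assign_class(matrix(c(92.86, 36.42), 1), model)),
               "Compact")
  # hand-computed L1 distances for a large loose organoid: nearest is class 1
  expect_equal(as.character(assign_class(matrix(c(127.44, 62.44), 1), model)),
               "Spherical")
  # equidistant between classes 1 and 2 -> lower index (Spherical) wins
  mid <- (c(107.33, 50.50) + c(92.86, 36.42)) / 2
  expect_equal(as.character(assign_class(matrix(mid, 1), model)),
               "Spherical")
  # data-frame records with ASA in um^2 are rescaled automatically
  rec <- data.frame(RGYR_um = 127.44, ASA_um2 = 62.44e4)
  expect_equal(as.character(assign_class(rec, model)), "Spherical")
})

test_that("degenerate inputs are rejected with informative errors", {
  expect_error(fit_kmedians(cbind(1:3, 1:3), k = 4), "distinct")
  expect_error(fit_kmedians(matrix(1:9, 3, 3)), "two columns")
  pts <- rbind(c(1, 1), c(1, 1), c(2, 2), c(3, 3), c(4, 4))
  m <- fit_kmedians(pts, k = 4, seed = 1)  # duplicates allowed if >= k distinct
  expect_equal(m$k, 4)
})
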