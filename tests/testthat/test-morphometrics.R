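test_that("projection diameters of simple configurations are exact", {
  single <- make_fixture("single", r = 7)
  for (pl in c("xy", "yz", "xz")) {
    expect_equal(projection_diameter(single, pl), 14)
  }
  expect_equal(organoid_diameter(single), 14)
  two <- organoid_snapshot(data.frame(id = 1:2, x = c(0, 14), y = 0, z = 0,
                                      radius = 7))
  expect_equal(projection_diameter(two, "xy"), 28)
  expect_equal(projection_diameter(two, "xz"), 28)
  expect_equal(projection_diameter(two, "yz"), 14)
  expect_equal(organoid_diameter(two), (28 + 14 + 28) / 3)
})

test_that("diameter is invariant under coordinate permutations and exceeds the center extent", {
  snap <- random_snapshot(40, seed = 5)
  d0 <- organoid_diameter(snap)
  perm <- snap
  perm$cells[, c("x", "y", "z")] <- snap$cells[, c("z", "x", "y")]
  expect_equal(organoid_diameter(perm), d0, tolerance = 1e-12)
  centers_extent <- max(dist(as.matrix(snap$cells[, c("x", "y")])))
  expect_gte(projection_diameter(snap, "xy"), centers_extent)
})

test_that("the pruned Feret computation equals the brute-force pair scan", {
  for (seed in 1:5) {
    snap <- random_snapshot(80, box = 40, seed = seed)
    p <- as.matrix(snap$cells[, c("x", "y")])
    r <- snap$cells$radius
    brute <- max(as.matrix(dist(p)) + outer(r, r, "+"), 2 * max(r))
    expect_equal(projection_diameter(snap, "xy"), brute, tolerance = 1e-12)
  }
})

test_that("radius of gyration matches closed forms and brute force", {
  # all centers coincident -> 0
  same <- organoid_snapshot(data.frame(id = 1:3, x = 5, y = -2, z = 1,
                                       radius = c(3, 4, 5)))
  expect_equal(radius_of_gyration(same), 0)
  # 8 cube corners at half-edge a -> a * sqrt(3)
  for (a in c(1, 5, 12.5)) {
    expect_equal(radius_of_gyration(make_fixture("cube", half_edge = a)),
                 a * sqrt(3), tolerance = 1e-12)
  }
  # brute-force recomputation on random snapshots, and invariances
  for (seed in 1:5) {
    snap <- random_snapshot(50, seed = seed)
    pos <- as.matrix(snap$cells[, c("x", "y", "z")])
    ctr <- colMeans(pos)
    brute <- sqrt(sum(sweep(pos, 2, ctr)^2) / nrow(pos))
    expect_equal(radius_of_gyration(snap), brute, tolerance = 1e-12)
    shifted <- snap
    shifted$cells[, c("x", "y", "z")] <-
      sweep(pos, 2, c(100, -50, 3), "+")
    expect_equal(radius_of_gyration(shifted), brute, tolerance = 1e-9)
    th <- 0.7
    rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    rotated <- snap
    rotated$cells[, c("x", "y", "z")] <- pos %*% rot
    expect_equal(radius_of_gyration(rotated), brute, tolerance = 1e-9)
  }
})

test_that("ASA of an isolated cell is exactly its sphere area", {
  for (r in c(3, 7, 11)) {
    snap <- make_fixture("single", r = r)
    expect_equal(accessible_surface_area(snap, seed = 1), 4 * pi * r^2)
  }
})

test_that("two-sphere ASA agrees with the spherical-cap closed form", {
  # equal spheres radius R at distance d < 2R lose caps of height R - d/2
  with_seed(123, {
    for (k in 1:20) {
      R <- runif(1, 4, 10)
      d <- runif(1, 0.5 * R, 1.95 * R)
      snap <- organoid_snapshot(data.frame(id = 1:2, x = c(0, d), y = 0,
                                           z = 0, radius = R))
      n_pts <- 500
      est <- accessible_surface_area(snap, n_points = n_pts, seed = k)
      h <- R - d / 2
      exact <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
      # binomial error of the survival fraction on each sphere
      p_surv <- 1 - h / (2 * R)
      se <- sqrt(2) * 4 * pi * R^2 * sqrt(p_surv * (1 - p_surv) / n_pts)
      expect_lt(abs(est - exact), 3 * se + 1e-9)
    }
  })
})

test_that("two-sphere ASA is non-increasing as the overlap deepens", {
  ds <- seq(13.5, 4, by = -0.5)
  vals <- vapply(ds, function(d) {
    snap <- organoid_snapshot(data.frame(id = 1:2, x = c(0, d), y = 0, z = 0,
                                         radius = 7))
    accessible_surface_area(snap, n_points = 2000, seed = 5)
  }, numeric(1))
  # allow tiny Monte-Carlo wiggle
  expect_true(all(diff(vals) <= 4 * pi * 49 * 0.02))
  expect_lt(vals[length(vals)], vals[1])
})

test_that("a buried cell contributes almost nothing to the ASA", {
  sh <- make_fixture("shell", r = 7)
  contrib <- accessible_surface_area(sh, seed = 1, per_cell = TRUE)
  expect_lt(contrib[1] / (4 * pi * 49), 0.05)
  expect_equal(sum(contrib), accessible_surface_area(sh, seed = 1))
})

test_that("ASA is translation invariant and bounded by the total membrane area", {
  snap <- random_snapshot(25, box = 15, seed = 9)
  a0 <- accessible_surface_area(snap, seed = 4)
  moved <- snap
  moved$cells[, c("x", "y", "z")] <-
    sweep(as.matrix(snap$cells[, c("x", "y", "z")]), 2, c(30, -12, 7), "+")
  expect_equal(accessible_surface_area(moved, seed = 4), a0,
               tolerance = 1e-9)
  expect_lte(a0, sum(4 * pi * snap$cells$radius^2))
  # per-cell direction streams: the estimate ignores row order
  shuffled <- snap
  shuffled$cells <- snap$cells[sample(nrow(snap$cells)), ]
  shuffled <- organoid_snapshot(shuffled$cells)
  expect_equal(accessible_surface_area(shuffled, seed = 4), a0,
               tolerance = 1e-9)
})

test_that("increasing the ASA sample size shrinks the Monte-Carlo error", {
  snap <- organoid_snapshot(data.frame(id = 1:2, x = c(0, 8), y = 0, z = 0,
                                       radius = 7))
  h <- 7 - 4
  exact <- 2 * (4 * pi * 49 - 2 * pi * 7 * h)
  err <- function(n_pts) {
    ests <- vapply(1:8, function(s) {
      accessible_surface_area(snap, n_points = n_pts, seed = s)
    }, numeric(1))
    sqrt(mean((ests - exact)^2))
  }
  # ~ sqrt(10) shrinkage going from 500 to 5000 points; allow slack
  expect_lt(err(5000), err(500))
})

test_that("morphometrics records are finite, consistent and well scaled", {
  snap <- make_fixture("chain", n = 4, r = 7)
  rec <- morphometrics(snap, seed = 2)
  expect_true(all(is.finite(unlist(rec))))
  expect_equal(rec$n_cells, 4L)
  expect_equal(rec$ASA_1e4_um2, rec$ASA_um2 / 1e4)
  expect_equal(rec$RGYR_um, radius_of_gyration(snap))
  expect_gte(rec$D_um, 14)
})
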