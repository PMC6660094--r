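test_that("phase boundaries follow the 45/35/15/5 lifespan split", {
  # div_age 20 h: boundaries at 9, 16, 19, 20 h
  expect_equal(cell_phase(c(0, 8.9, 9, 15.9, 16, 18.9, 19, 20), 20),
               c("G1", "G1", "S", "S", "G2", "G2", "M", "M"))
  # the mapping is scale-free in age / div_age
  expect_equal(cell_phase(0.449 * 13, 13), "G1")
  expect_equal(cell_phase(0.951 * 13, 13), "M")
})

test_that("radius grows linearly from 0.65 r_max and saturates at r_max", {
  p <- simulation_params(r_max = 7, a_div = 20)
  expect_equal(cell_radius_at_age(0, 20, p), 0.65 * 7)
  expect_equal(cell_radius_at_age(0.95 * 20, 20, p), 7)
  expect_equal(cell_radius_at_age(20, 20, p), 7)  # capped
  mid <- cell_radius_at_age(0.475 * 20, 20, p)
  expect_equal(mid, 0.65 * 7 + 0.35 * 7 / 2)
  # g1 schedule completes growth at 45% of the lifespan
  p1 <- simulation_params(r_max = 7, a_div = 20, growth_schedule = "g1")
  expect_equal(cell_radius_at_age(9, 20, p1), 7)
})

test_that("arrest freezes the cycle clock but not (by default) cell growth", {
  p <- simulation_params(r_max = 7, a_div = 20)
  cells <- data.frame(id = 1:2, x = c(0, 50), y = 0, z = 0,
                      radius = 0.65 * 7, phase = "G1", age = 0, div_age = 20,
                      arrested = c(TRUE, FALSE), n_neighbors = 0L)
  snap <- organoid_snapshot(cells)
  adv <- advance_cycle(snap, dt = 1, p)
  expect_equal(adv$cells$age, c(0, 1))        # arrested clock frozen
  expect_equal(adv$cells$phase, c("G1", "G1"))
  rate <- 0.35 * 7 / (0.95 * 20)
  expect_equal(adv$cells$radius, rep(0.65 * 7 + rate, 2))  # both keep growing
  # freeze policy: the arrested cell's radius stays put as well
  pf <- simulation_params(r_max = 7, a_div = 20, arrest_growth = "freeze")
  advf <- advance_cycle(snap, dt = 1, pf)
  expect_equal(advf$cells$radius, 0.65 * 7 + c(0, rate))
})

test_that("contact inhibition counts strictly inside two cell diameters", {
  p <- simulation_params(r_max = 7, n_neigh = 6)
  # 1 center cell + 7 mature cells at distance 3 r_max = 21 um < 28 um
  with_seed(7, {
    dirs <- matrix(rnorm(21), 7, 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
  })
  cells <- data.frame(id = 1:8,
                      x = c(0, 21 * dirs[, 1]),
                      y = c(0, 21 * dirs[, 2]),
                      z = c(0, 21 * dirs[, 3]),
                      radius = 7)
  snap <- organoid_snapshot(cells)
  ci <- contact_inhibited(snap, p)
  expect_equal(ci$n_neighbors[1], 7L)
  expect_true(ci$inhibited[1])                      # 7 > 6
  expect_false(contact_inhibited(snap, simulation_params(
    r_max = 7, n_neigh = 7))$inhibited[1])          # 7 > 7 is false
  # a neighbor at exactly 4 r_max is not counted (strict inequality)
  pair <- organoid_snapshot(data.frame(id = 1:2, x = c(0, 28), y = 0, z = 0,
                                       radius = 7))
  expect_equal(contact_inhibited(pair, p)$n_neighbors, c(0L, 0L))
  # founder alone is never inhibited
  single <- make_fixture("single", r = 7)
  expect_false(contact_inhibited(single, simulation_params(
    n_neigh = 0))$inhibited)
})

test_that("the current-radius scope shrinks a newborn cell's neighborhood", {
  # neighbor at 20 um: inside 4 * 7 = 28 but outside 4 * 4.55 = 18.2
  cells <- data.frame(id = 1:2, x = c(0, 20), y = 0, z = 0,
                      radius = c(0.65 * 7, 7))
  snap <- organoid_snapshot(cells)
  cur <- contact_inhibited(snap, simulation_params(r_max = 7, n_neigh = 0,
                                                   inhibition_scope = "current"))
  expect_equal(cur$n_neighbors, c(0L, 1L))
  fix <- contact_inhibited(snap, simulation_params(r_max = 7, n_neigh = 0,
                                                   inhibition_scope = "r_max"))
  expect_equal(fix$n_neighbors, c(1L, 1L))
})

test_that("division places daughters symmetrically on the sampled axis", {
  p <- simulation_params(r_max = 7, a_div = 11, noise_frac = 0.05)
  mother <- data.frame(id = 5L, x = 1, y = 2, z = 3, radius = 7,
                       phase = "M", age = 11, div_age = 11,
                       arrested = FALSE, n_neighbors = 0L)
  # replay the generator's own draws to get the expected axis
  set.seed(99)
  theta <- runif(1, 0, pi)
  phi <- runif(1, 0, 2 * pi)
  axis <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  noise <- runif(2, -0.05, 0.05)
  set.seed(99)
  d <- divide_cell(mother, p)
  expect_equal(nrow(d), 2L)
  expect_equal(as.numeric(d[1, c("x", "y", "z")]),
               c(1, 2, 3) + 0.5 * 7 * axis)
  expect_equal(as.numeric(d[2, c("x", "y", "z")]),
               c(1, 2, 3) - 0.5 * 7 * axis)
  # midpoint is the mother's position, separation exactly r_max
  expect_equal(colMeans(as.matrix(d[, c("x", "y", "z")])),
               c(x = 1, y = 2, z = 3))
  expect_equal(as.numeric(dist(as.matrix(d[, c("x", "y", "z")]))), 7)
  # newborn state: age 0, phase G1, radius 0.65 r_max, jittered division age
  expect_equal(d$age, c(0, 0))
  expect_equal(d$phase, c("G1", "G1"))
  expect_equal(d$radius, rep(0.65 * 7, 2))
  expect_equal(d$div_age, 11 * (1 + noise))
  # daughters overlap (separation 7 < 2 * 4.55) so repulsion acts at birth
  expect_lt(7, 2 * d$radius[1])
})
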