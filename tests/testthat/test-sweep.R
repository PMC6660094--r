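# short-horizon study conditions so sweep tests run in seconds: gate on
# days 0-2 of growth from a fast-dividing founder
short_params <- simulation_params(a_div = 8, t_end = 48)
short_days <- c(0, 1, 2)

short_curve <- local({
  dmat <- vapply(1:3, function(s) {
    p <- simulation_params(r_max = 7, a_div = 8, n_neigh = 6, t_end = 48)
    traj <- run_simulation(p, seed = s, output_times = short_days * 24)
    vapply(traj$snapshots, organoid_diameter, numeric(1))
  }, numeric(3))
  m <- rowMeans(dmat)
  growth_curve(short_days, m, pmax(apply(dmat, 1, sd), 0.25 * m))
})

test_that("a triple is accepted against a curve built from its own runs", {
  grid <- data.frame(r_max = 7, a_div = 8, n_neigh = 6)
  sw <- run_sweep(grid, short_curve, replicates = 3, seed = 1,
                  base_params = short_params)
  expect_equal(nrow(sw$runs), 3L)
  expect_true(all(sw$runs$band_ok))
  expect_true(all(sw$runs$r2 > 0.9))
  expect_true(sw$triples$accepted)
})

test_that("a zero-width band rejects stochastic runs and bookkeeping holds", {
  zero_curve <- growth_curve(short_days, short_curve$mean_diameter_um,
                             rep(0, 3))
  grid <- expand.grid(r_max = 7, a_div = c(8, 10), n_neigh = c(4, 6))
  sw <- run_sweep(grid, zero_curve, replicates = 2, seed = 1,
                  base_params = short_params, early_stop = FALSE)
  expect_equal(nrow(sw$runs), nrow(grid) * 2L)
  expect_equal(nrow(sw$triples), nrow(grid))
  expect_false(any(sw$triples$accepted))
  expect_true(all(!sw$runs$accepted_run))
})

test_that("runs that leave the band upward are truncated early", {
  tiny_curve <- growth_curve(short_days, c(14, 20, 25), c(5, 2, 2))
  grid <- data.frame(r_max = 7, a_div = 8, n_neigh = 20)
  sw <- run_sweep(grid, tiny_curve, replicates = 2, seed = 1,
                  base_params = short_params)
  expect_true(all(sw$runs$truncated))
  expect_true(all(is.na(sw$runs$r2)))
  expect_false(any(sw$triples$accepted))
})

test_that("heatmaps cover the full grid axes and only accepted entries", {
  grid <- expand.grid(r_max = 7, a_div = c(8, 10), n_neigh = c(6, 20))
  curve_loose <- growth_curve(short_days, short_curve$mean_diameter_um,
                              short_curve$std_um * 2)
  sw <- run_sweep(grid, curve_loose, replicates = 2, seed = 2,
                  base_params = short_params)
  hm <- emit_heatmap(sw, 7, "r2")
  expect_equal(dim(hm), c(2L, 2L))
  expect_equal(rownames(hm), c("8", "10"))
  expect_equal(colnames(hm), c("6", "20"))
  n_acc <- sum(sw$triples$accepted)
  expect_equal(attr(hm, "n_accepted"), n_acc)
  expect_equal(sum(!is.na(hm)), n_acc)
  # a value heatmap carries replicate means of the final morphometrics
  hn <- emit_heatmap(sw, 7, "n_cells")
  expect_equal(sum(!is.na(hn)), n_acc)
})

test_that("the morphochart indexes exactly the accepted triples", {
  grid <- expand.grid(r_max = 7, a_div = 8, n_neigh = c(6, 20))
  curve_loose <- growth_curve(short_days, short_curve$mean_diameter_um,
                              short_curve$std_um * 2)
  sw <- run_sweep(grid, curve_loose, replicates = 3, seed = 3,
                  base_params = short_params)
  outdir <- file.path(tempdir(), "chart_test")
  idx <- emit_morphochart(sw, 7, outdir)
  acc <- sw$triples[sw$triples$accepted, ]
  expect_equal(nrow(idx), nrow(acc))
  if (nrow(idx) > 0) {
    expect_setequal(paste(idx$a_div, idx$n_neigh),
                    paste(acc$a_div, acc$n_neigh))
    expect_true(all(file.exists(file.path(outdir, idx$snapshot))))
    expect_true(all(file.exists(file.path(outdir, idx$silhouette))))
    # the representative replicate is the median-R^2 one
    sub <- sw$runs[sw$runs$a_div == idx$a_div[1] &
                     sw$runs$n_neigh == idx$n_neigh[1], ]
    expect_equal(idx$replicate[1],
                 sub$replicate[order(sub$r2)[2]])
  }
  expect_true(file.exists(file.path(outdir, "index.csv")))
})

test_that("an empty acceptance set still yields a complete, empty chart", {
  zero_curve <- growth_curve(short_days, short_curve$mean_diameter_um,
                             rep(0, 3))
  grid <- data.frame(r_max = 7, a_div = 8, n_neigh = 6)
  sw <- run_sweep(grid, zero_curve, replicates = 2, seed = 1,
                  base_params = short_params, early_stop = FALSE)
  outdir <- file.path(tempdir(), "chart_empty")
  idx <- emit_morphochart(sw, 7, outdir)
  expect_equal(nrow(idx), 0L)
  hm <- emit_heatmap(sw, 7)
  expect_equal(attr(hm, "n_accepted"), 0L)
  expect_true(all(is.na(hm)))
})
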