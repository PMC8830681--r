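test_that("rhythm_value matches the analytic oscillator", {
  tr <- ground_truth_rhythm(2, 0, 24, 0, 10)
  expect_equal(rhythm_value(tr, 0, 0), 12)
  expect_equal(rhythm_value(tr, 12, 0), 8)

  damped <- ground_truth_rhythm(2, 0.05, 24, 0, 0)
  expect_equal(rhythm_value(damped, 24, 0), 2 * exp(-1.2))

  # vectorized evaluation agrees with pointwise direct evaluation
  tr2 <- ground_truth_rhythm(1.5, 0.02, 26, pi / 3, 5, trend_slope = 0.1)
  tt <- seq(16, 40, by = 4)
  direct <- vapply(tt, function(t) {
    5 + 0.1 * (t - 16) + 1.5 * exp(-0.02 * (t - 16)) *
      cos(2 * pi * (t - 16) / 26 + pi / 3)
  }, numeric(1))
  expect_equal(rhythm_value(tr2, tt, 16), direct)
})

test_that("invalid rhythm parameters are rejected", {
  expect_error(ground_truth_rhythm(2, 0, -24, 0, 10), "period")
  expect_error(ground_truth_rhythm(-1, 0, 24, 0, 10), "amplitude")
  expect_error(ground_truth_rhythm(2, 0, 24, 0, 10, noise_sd = -1),
               "noise_sd")
  expect_error(ground_truth_rhythm(NaN, 0, 24, 0, 10), "finite")
  tr <- ground_truth_rhythm(2, 0, 24, 0, 10)
  expect_error(rhythm_value(tr, Inf, 0), "finite")
})

test_that("render_scene produces the specified background and is seeded", {
  spec <- scene_spec(128, 96, background = 50, noise_sd = 2, seed = 3)
  sc <- render_scene(spec)
  n <- length(sc$image)
  expect_lt(abs(mean(sc$image) - 50), 3 * 2 / sqrt(n))
  expect_identical(sc$image, render_scene(spec)$image)
  expect_equal(nrow(sc$truth), 0)
})

test_that("rendered disc area matches the rasterization oracle", {
  cells <- tibble::tibble(x = 40, y = 40, radius = 10, clump_size = 1L,
                          intensity = 50)
  sc <- render_scene(scene_spec(80, 80, cells, background = 5,
                                noise_sd = 0, seed = 1))
  expect_equal(sc$truth$area_px, oracle_disc_area(80, 80, 40, 40, 10))
  # close to pi r^2 as a sanity bound on the oracle itself
  expect_lt(abs(sc$truth$area_px - pi * 100), 12)

  clump <- tibble::tibble(x = 30, y = 60, radius = 8, clump_size = 3L,
                          intensity = 50)
  sc3 <- render_scene(scene_spec(160, 120, clump, background = 5,
                                 noise_sd = 0, seed = 1))
  expect_equal(sc3$truth$area_px,
               oracle_disc_area(160, 120, 30, 60, 8, clump_size = 3))
})

test_that("scenes with overlapping entries or out-of-frame cells fail", {
  two <- tibble::tibble(x = c(40, 52), y = 40, radius = 10,
                        clump_size = 1L, intensity = 50)
  expect_error(render_scene(scene_spec(100, 100, two, seed = 1)),
               "overlap")
  edge <- tibble::tibble(x = 5, y = 40, radius = 10, clump_size = 1L,
                         intensity = 50)
  expect_error(scene_spec(100, 100, edge), "inside the frame")
})

test_that("rendered object means track the specified true mean", {
  # noise sd 2% of signal, radius >= 8 px: recovered mean within 2%
  sc <- make_test_scene(n_cells = 9, intensity = 500, noise_sd = 10,
                        seed = 11, width = 400, height = 400)
  expect_equal(nrow(sc$truth), 9)
  for (i in seq_len(9)) {
    m <- circaphage:::cell_entry_mask(400, 400, sc$truth$x[i], sc$truth$y[i],
                                      10, 1)
    expect_lt(abs(mean(sc$image[m]) - 500) / 500, 0.02)
  }
})

test_that("the simulated experiment follows the sampling design", {
  des <- experiment_design(start = 16, interval = 4, span = 24,
                           replicates = 3, cells_per_image = 5, seed = 2)
  expect_equal(design_timepoints(des), c(16, 20, 24, 28, 32, 36, 40))

  flat <- ground_truth_rhythm(0, 0, 24, 0, 400)
  sim <- simulate_phagocytosis_experiment(des, flat, width = 256,
                                          height = 256)
  expect_equal(nrow(sim$scenes), 7 * 3)
  expect_true(all(sim$timepoint_truth$expected_intensity == 400))
  # ground-truth conservation
  expect_equal(nrow(sim$cell_truth), 7 * 3 * 5)

  # zenith of the expected intensity at PS32 when the phase says so
  osc <- ground_truth_rhythm(100, 0, 24, -2 * pi * (32 - 16) / 24, 400)
  sim2 <- simulate_phagocytosis_experiment(des, osc, width = 256,
                                           height = 256)
  tt <- sim2$timepoint_truth
  expect_equal(tt$time_ps[which.max(tt$expected_intensity)], 32)
})

test_that("disaccharide simulation respects vocabulary and rhythm", {
  des <- experiment_design(replicates = 4, seed = 9)
  flat <- ground_truth_rhythm(0, 0, 24, 0, 5)
  sp <- tibble::tibble(class = "HS", code = "NS", truth = list(flat))
  tab <- simulate_disaccharide_series(sp, des)
  expect_true(all(tab$raw_ng == 5))
  expect_equal(nrow(tab), 7 * 4)

  # antiphase pair with equal equilibria: noiseless totals are constant
  a <- ground_truth_rhythm(2, 0, 24, 0, 6)
  b <- ground_truth_rhythm(2, 0, 24, pi, 6)
  sp2 <- tibble::tibble(class = "HS", code = c("0S", "6S"),
                        truth = list(a, b))
  tab2 <- simulate_disaccharide_series(sp2, des)
  totals <- tapply(tab2$raw_ng, paste(tab2$time_ps, tab2$replicate), sum)
  expect_equal(as.vector(totals), rep(12, length(totals)))

  bad <- tibble::tibble(class = "HS", code = "3S", truth = list(flat))
  expect_error(simulate_disaccharide_series(bad, des),
               "unknown sulfation code")
})

test_that("standard-curve simulation is exact without noise and seeded", {
  tab <- simulate_standard_curve(2, 100, c(0, 10), noise_sd = 0)
  expect_equal(tab$fluorescence, c(100, 120))
  t1 <- simulate_standard_curve(3, 5, 0:5, noise_sd = 2, seed = 7)
  t2 <- simulate_standard_curve(3, 5, 0:5, noise_sd = 2, seed = 7)
  expect_identical(t1, t2)
  expect_error(simulate_standard_curve(0, 1, 0:3), "nonzero")
})

test_that("luminescence traces have the expected zenith structure", {
  des <- experiment_design(start = 0, interval = 4, span = 72, seed = 4)
  sus <- ground_truth_rhythm(5, 0, 24, 0, 0)
  tr <- simulate_luminescence_trace(sus, des, step = 0.25)
  peaks <- tr$time_ps[c(which.max(tr$value[tr$time_ps < 12]),
                        12 / 0.25 + which.max(tr$value[tr$time_ps >= 12 &
                                                       tr$time_ps < 36]),
                        36 / 0.25 + which.max(tr$value[tr$time_ps >= 36 &
                                                       tr$time_ps < 60]))]
  expect_equal(diff(peaks), c(24, 24))
  expect_equal(peaks[1], 0)

  damped <- ground_truth_rhythm(5, 0.03, 24, 0, 0)
  trd <- simulate_luminescence_trace(damped, des, step = 0.25)
  zen <- vapply(c(0, 24, 48), function(z) {
    seg <- trd[trd$time_ps >= z & trd$time_ps < z + 24, ]
    max(seg$value)
  }, numeric(1))
  expect_true(all(diff(zen) < 0))
})

test_that("generators are pure functions of spec and seed", {
  des <- experiment_design(replicates = 2, cells_per_image = 4, seed = 31)
  tr <- ground_truth_rhythm(50, 0, 24, 0, 300, noise_sd = 5)
  s1 <- simulate_rhythm_series(tr, des, seed = 8)
  s2 <- simulate_rhythm_series(tr, des, seed = 8)
  expect_identical(s1, s2)
  sim1 <- simulate_phagocytosis_experiment(des, tr, width = 200,
                                           height = 200)
  sim2 <- simulate_phagocytosis_experiment(des, tr, width = 200,
                                           height = 200)
  expect_identical(sim1$scenes$scene[[5]]$image, sim2$scenes$scene[[5]]$image)
  expect_identical(sim1$cell_truth, sim2$cell_truth)
})
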