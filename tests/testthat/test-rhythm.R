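test_that("detrending removes a pure line to machine precision", {
  d <- tibble::tibble(time_ps = rep(seq(16, 40, 4), 2),
                      replicate = rep(1:2, each = 7))
  d$value <- 2 * d$time_ps + 1
  out <- preprocess_series(d, detrend = TRUE, smooth = FALSE)
  expect_lt(max(abs(out$value)), 1e-10)
  expect_equal(unname(attr(out, "trend")), c(1, 2), tolerance = 1e-10)

  const <- dplyr::mutate(d, value = 5)
  outc <- preprocess_series(const, detrend = TRUE, smooth = FALSE)
  expect_lt(max(abs(outc$value)), 1e-10)
})

test_that("smoothing matches the direct (1,2,1)/4 convolution oracle", {
  tp <- seq(16, 40, 4)
  d <- tibble::tibble(time_ps = tp, replicate = 1,
                      value = cos(2 * pi * tp / 24) + 0.5 * tp)
  out <- preprocess_series(d, detrend = FALSE, smooth = TRUE)
  expect_equal(out$value, oracle_smooth121(d$value), tolerance = 1e-12)

  # replicate deviations are preserved around the smoothed means
  d2 <- tibble::tibble(time_ps = rep(tp, each = 2), replicate = rep(1:2, 7))
  d2$value <- sin(d2$time_ps / 5) + ifelse(d2$replicate == 1, 0.1, -0.1)
  out2 <- preprocess_series(d2, detrend = FALSE, smooth = TRUE)
  devs <- out2$value[out2$replicate == 1] - out2$value[out2$replicate == 2]
  expect_equal(devs, rep(0.2, 7), tolerance = 1e-12)
  expect_error(preprocess_series(d[1:2, ]), "3 distinct")
})

test_that("the oscillator fit recovers noiseless parameters", {
  tr <- ground_truth_rhythm(2, 0.05, 24, 0, 10)
  d <- tibble::tibble(time_ps = seq(0, 48, 2), replicate = 1L,
                      value = rhythm_value(tr, seq(0, 48, 2)))
  fit <- fit_eho(d)
  expect_lt(abs(fit$period - 24), 0.1)
  expect_lt(abs(fit$ac_coef - 0.05), 0.005)
  expect_lt(abs(fit$amplitude - 2) / 2, 0.01)
  expect_lt(abs(fit$equilibrium - 10), 0.1)
  expect_true(fit$circadian)
})

test_that("constant and ultradian series are not circadian", {
  d <- tibble::tibble(time_ps = seq(16, 40, 4), replicate = 1L, value = 3)
  fit <- fit_eho(d)
  expect_lt(fit$amplitude, 1e-6)
  expect_false(fit$circadian)

  ultra <- ground_truth_rhythm(2, 0, 12, 0, 10)
  tps <- seq(0, 48, 2)
  du <- tibble::tibble(time_ps = tps, replicate = 1L,
                       value = rhythm_value(ultra, tps))
  fitu <- fit_eho(du)
  expect_false(fitu$circadian)
  expect_true("period" %in% fitu$reasons)
})

test_that("fit SSE never exceeds the best constant model", {
  set.seed(88)
  for (i in 1:10) {
    d <- tibble::tibble(time_ps = seq(0, 48, 4), replicate = 1L,
                        value = rnorm(13))
    fit <- fit_eho(d)
    expect_lte(fit$sse, fit$sse_constant + 1e-9)
  }
})

test_that("the Kendall fit p-value matches the exhaustive-permutation oracle", {
  set.seed(12)
  for (i in 1:5) {
    y <- sample(seq_len(7) + rnorm(7, 0, 0.01))
    yhat <- y + rnorm(7, 0, 2)
    expect_equal(rhythm_pvalue(yhat, y),
                 oracle_kendall_p(yhat, y), tolerance = 1e-12)
  }
  # perfect monotone agreement at n = 7: exact tail of tau = 1 is 1/7!
  y <- 1:7 + 0
  expect_equal(rhythm_pvalue(y, y), 1 / factorial(7), tolerance = 1e-12)

  expect_equal(rhythm_pvalue(rep(1, 10), rnorm(10)), 1)
  expect_gte(rhythm_pvalue(10:1 + 0, 1:10 + rnorm(10, 0, 0.01)), 0.5)
  expect_equal(rhythm_pvalue(c(1, 2), c(1, 2)), 1)  # too few points
})

test_that("BH and BY adjustments match the step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  adj <- adjust_pvalues(p)
  expect_equal(adj$p_bh, rep(0.04, 4))
  expect_equal(adj$p_by, rep(0.04 * 25 / 12, 4))
  expect_equal(adjust_pvalues(0.03)$p_by, 0.03)

  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    adj <- adjust_pvalues(p)
    expect_equal(adj$p_bh, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj$p_by, oracle_by(p), tolerance = 1e-12)
    expect_true(all(adj$p_bh <= adj$p_by + 1e-15))
    expect_true(all(adj$p_bh >= p - 1e-15))
    expect_true(all(adj$p_by <= 1))
    # order preservation
    expect_true(all(diff(adj$p_bh[order(p)]) >= -1e-15))
  }
})

test_that("classification gates produce the right reason codes", {
  base <- fit_eho(tibble::tibble(
    time_ps = seq(0, 48, 2), replicate = 1L,
    value = rhythm_value(ground_truth_rhythm(2, 0.05, 26, 0, 10),
                         seq(0, 48, 2))
  ))
  expect_true(base$circadian)
  expect_equal(base$reasons, character(0))
  expect_lt(abs(base$period - 26), 0.1)

  tweak <- function(fit, ...) {
    mods <- list(...)
    fit[names(mods)] <- mods
    cl <- classify_rhythm(fit)
    cl
  }
  expect_equal(tweak(base, ac_coef = 0.30)$reasons, "ac_coefficient")
  expect_equal(tweak(base, period = 17.9)$reasons, "period")
  expect_false(tweak(base, p_by = 0.2)$circadian)
  expect_equal(tweak(base, ac_coef = 0.15)$reasons, character(0))  # inclusive
})

test_that("zenith and nadir land on the cosine extrema", {
  tr <- ground_truth_rhythm(2, 0, 24, 0, 10)
  tps <- seq(16, 40, 2)
  fit <- fit_eho(tibble::tibble(time_ps = tps, replicate = 1L,
                                value = rhythm_value(tr, tps, t0 = 16)))
  zn <- zenith_nadir(fit)
  expect_lt(min(abs(zn$zenith_ps - c(16, 40))), 0.05)  # both ends peak
  expect_lt(abs(zn$nadir_ps - 28), 0.05)

  # damped fit: extrema must equal the dense-grid argmax/argmin
  trd <- ground_truth_rhythm(2, 0.04, 24, 1, 10)
  fitd <- fit_eho(tibble::tibble(time_ps = seq(0, 48, 2), replicate = 1L,
                                 value = rhythm_value(trd, seq(0, 48, 2))))
  grid <- seq(fitd$window[1], fitd$window[2], 0.01)
  yy <- eho_predict(fitd, grid)
  expect_equal(fitd$zenith_ps, grid[which.max(yy)])
  expect_equal(fitd$nadir_ps, grid[which.min(yy)])

  # a window that excludes the analytic peak clips to the boundary
  znw <- zenith_nadir(fitd, window = c(30, 34))
  expect_true(znw$clipped)
})

test_that("time conversions reproduce the printed pairings and round-trip", {
  expect_equal(time_convert(0, "index", "PS"), 16)
  expect_equal(time_convert(32, "PS", "CT"), 20)
  expect_equal(time_convert(20, "PS", "CT"), 8)
  expect_equal(time_convert(8, "CT", "PS"), 20)
  for (x in seq(-10, 50, 7.5)) {
    expect_equal(time_convert(time_convert(x, "PS", "CT"), "CT", "PS"), x)
    expect_equal(time_convert(time_convert(x, "index", "CT"), "CT", "index"),
                 x)
  }
  expect_error(time_convert(1, "PS", "zulu"), "bases")
})

test_that("catalog fitting adjusts p-values across all series", {
  dat <- dplyr::bind_rows(
    make_test_series("a", seed = 1), make_test_series("b", seed = 2),
    make_test_series("flat", amplitude = 0, noise_sd = 0.2, seed = 3)
  )
  res <- fit_rhythms(dat, detrend = FALSE, smooth = FALSE)
  expect_equal(nrow(res), 3)
  adj <- adjust_pvalues(res$p)
  expect_equal(res$p_bh, adj$p_bh)
  expect_equal(res$p_by, adj$p_by)
  expect_true(all(res$p_by >= res$p - 1e-15))
  expect_equal(res$zenith_ct, res$zenith_ps - 12)
})

test_that("tidiers and plots expose the fit", {
  fit <- fit_eho(make_test_series(seed = 4, noise_sd = 0.05))
  td <- tidy(fit)
  expect_equal(td$term[1:2], c("amplitude", "ac_coef"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("period", "p", "circadian") %in% names(gl)))
  aug <- augment(fit)
  expect_equal(aug$.resid, aug$value - aug$.fitted)
  expect_s3_class(autoplot(fit), "ggplot")
})
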