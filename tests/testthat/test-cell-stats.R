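test_that("preprocessing removes sub-background values then logs", {
  tab <- tibble::tibble(time_ps = 16, replicate = 1,
                        corrected_mean = c(0.5, 10, 100))
  out <- preprocess_intensities(tab, background_signal = 1)
  expect_equal(out$log10_intensity, c(1, 2))
  removed <- attr(out, "removed")
  expect_equal(nrow(removed), 1)
  expect_true(removed$below_threshold_removed)
  expect_false(removed$iqr_removed)
})

test_that("IQR fences match the brute-force quantile oracle", {
  # logged values {1,2,3,4,100}: Q1=2, Q3=4, fences [-1, 7] -> 100 removed
  tab <- tibble::tibble(time_ps = 20, replicate = 1,
                        corrected_mean = 10^c(1, 2, 3, 4, 100))
  out <- preprocess_intensities(tab, background_signal = 0)
  expect_equal(sort(out$log10_intensity), c(1, 2, 3, 4))
  expect_equal(oracle_iqr_fences(c(1, 2, 3, 4, 100)), c(-1, 7))

  # randomized agreement with the oracle, per timepoint
  set.seed(401)
  for (rep in 1:20) {
    v <- rlnorm(30, 3, 1)
    tab <- tibble::tibble(time_ps = 16, replicate = 1, corrected_mean = v)
    out <- preprocess_intensities(tab, background_signal = 0)
    fen <- oracle_iqr_fences(log10(v))
    keep <- log10(v) >= fen[1] & log10(v) <= fen[2]
    expect_equal(sort(out$log10_intensity), sort(log10(v)[keep]))
  }
})

test_that("degenerate timepoints skip the IQR step and equal values survive", {
  tab <- tibble::tibble(time_ps = c(16, 16, 20, 20, 20),
                        replicate = 1,
                        corrected_mean = c(5, 500, 7, 7, 7))
  out <- preprocess_intensities(tab, background_signal = 0)
  expect_equal(attr(out, "skipped_iqr"), 16)
  expect_equal(nrow(out), 5)  # IQR = 0 keeps the identical values
})

test_that("preprocessing is a pure filter", {
  set.seed(17)
  tab <- tibble::tibble(time_ps = rep(c(16, 20, 24), each = 40),
                        replicate = rep(1:4, 30),
                        corrected_mean = rlnorm(120, 2, 0.8))
  out <- preprocess_intensities(tab, background_signal = 0.5)
  expect_true(all(out$corrected_mean %in% tab$corrected_mean))
  expect_equal(out$log10_intensity, log10(out$corrected_mean))
  removed <- attr(out, "removed")
  expect_equal(nrow(out) + nrow(removed), nrow(tab))
  expect_true(all(xor(removed$below_threshold_removed, removed$iqr_removed)))
})

test_that("welch_test matches the direct formula and its oracle", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  wt <- welch_test(x, y)
  expect_equal(wt$t, -2.19089023, tolerance = 1e-7)
  expect_equal(wt$df, 6)
  expect_equal(wt$p, 0.0710, tolerance = 1e-3)
  orc <- oracle_welch(x, y)
  expect_equal(wt$t, orc$t, tolerance = 1e-12)
  expect_equal(wt$p, orc$p, tolerance = 1e-12)

  same <- welch_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  sw <- welch_test(y, x)
  expect_equal(sw$t, -wt$t)
  expect_equal(sw$p, wt$p)

  deg1 <- welch_test(c(2, 2, 2), c(2, 2))
  expect_true(deg1$degenerate)
  expect_equal(deg1$p, 1)
  deg2 <- welch_test(c(2, 2, 2), c(3, 3))
  expect_equal(deg2$p, 0)
})

test_that("welch_test keeps its nominal type-I error under the null", {
  set.seed(2024)
  reps <- 2000
  p <- vapply(seq_len(reps), function(i) {
    welch_test(rnorm(10), rnorm(10))$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("hedges_g applies the small-sample correction", {
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  hg <- hedges_g(x, y)
  # d = -2 / sqrt(5/3) = -1.549..., J = 20/23
  expect_equal(hg$g, (-2 / sqrt(5 / 3)) * (20 / 23), tolerance = 1e-12)
  expect_equal(hg$g, -1.347, tolerance = 1e-3)
  expect_equal(hg$effect_class, "large")
  expect_equal(hg$g, oracle_hedges(x, y), tolerance = 1e-12)

  same <- hedges_g(x, x)
  expect_equal(same$g, 0)
  expect_equal(same$effect_class, "negligible")

  expect_error(hedges_g(c(1, 1), c(1, 1)), "pooled variance")
})

test_that("effect classes follow the 0.2 / 0.5 / 0.8 bands", {
  cls <- circaphage:::effect_class(c(0.1, -0.3, 0.6, -0.6, 1.2, 0.2, 0.5))
  expect_equal(cls, c("negligible", "small", "medium", "medium", "large",
                      "negligible", "small"))
})

test_that("hedges_g is nearly unbiased at true d = 1", {
  set.seed(99)
  g <- vapply(seq_len(2000), function(i) {
    hedges_g(rnorm(20, 1), rnorm(20, 0))$g
  }, numeric(1))
  expect_lt(abs(mean(g) - 1), 0.05)
})

test_that("joint decisions require both a small p and a large effect", {
  expect_true(joint_decision(1e-17, 0.724791))
  expect_false(joint_decision(0.006426, 0.361095))
  expect_false(joint_decision(0.5, 2.0))
  expect_true(joint_decision(0.01, -0.9))      # sign-free magnitude gate
  expect_false(joint_decision(0.01, 0.9, g_min = 2.0))
  expect_error(joint_decision(1.5, 1), "\\[0, 1\\]")
})

test_that("joint decisions are monotone in p and |g|", {
  set.seed(7)
  for (i in 1:100) {
    p <- runif(1); g <- runif(1, -3, 3)
    v <- joint_decision(p, g)
    if (v) {
      expect_true(joint_decision(p / 2, g))
      expect_true(joint_decision(p, g * 1.5))
    } else {
      expect_false(joint_decision(min(p * 1.5, 1), g / 2))
    }
  }
})

test_that("timepoint summaries average replicates then timepoints", {
  tab <- tibble::tibble(time_ps = 16, replicate = c(1, 1, 2, 2, 3, 3),
                        log10_intensity = c(1.5, 2.5, 3, 3, 4, 4))
  s <- timepoint_summary(tab)
  expect_equal(s$replicate_means$mean, c(2, 3, 4))
  expect_equal(s$timepoint_means$mean, 3)

  one <- tibble::tibble(time_ps = 20, replicate = 1,
                        log10_intensity = c(2, 4))
  s1 <- timepoint_summary(one)
  expect_equal(s1$timepoint_means$mean, s1$replicate_means$mean)
})

test_that("compare_groups reproduces the two-sample machinery end to end", {
  set.seed(5)
  dat <- tibble::tibble(
    grp = rep(c("PS20", "PS32"), c(60, 50)),
    log10_intensity = c(rnorm(60, 2.0, 0.3), rnorm(50, 2.4, 0.3))
  )
  cmp <- compare_groups(dat, group = "grp", groups = c("PS20", "PS32"))
  x <- dat$log10_intensity[dat$grp == "PS20"]
  y <- dat$log10_intensity[dat$grp == "PS32"]
  expect_equal(cmp$p, oracle_welch(x, y)$p, tolerance = 1e-12)
  expect_equal(cmp$g, oracle_hedges(x, y), tolerance = 1e-12)
  expect_equal(cmp$significant,
               cmp$p < 0.05 && abs(cmp$g) >= 0.5)
})
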