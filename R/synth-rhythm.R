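#' Ground-truth rhythm parameters
#'
#' Bundles the parameters of the damped-cosine (extended harmonic oscillator)
#' generative model used by every simulator in the package:
#' \deqn{y(t) = C + b (t - t_0) + A e^{-\gamma (t - t_0)}
#'   \cos\!\left(\frac{2\pi (t - t_0)}{\tau} + \phi\right)}
#' where `A` is the amplitude, `gamma` the amplitude-change (AC) coefficient in
#' inverse hours (0 = sustained, positive = damped), `tau` the period in hours,
#' `phi` the phase in radians, `C` the equilibrium level, and `b` an optional
#' linear trend.
#'
#' @param amplitude Oscillation amplitude `A` (intensity units or ng/cell);
#'   must be >= 0.
#' @param ac_coef Amplitude-change coefficient `gamma` in 1/h.
#' @param period Period `tau` in hours; must be > 0.
#' @param phase Phase `phi` in radians.
#' @param equilibrium Midline level `C`, same units as `amplitude`.
#' @param trend_slope Linear trend in units per hour (default 0).
#' @param noise_sd Gaussian noise standard deviation added by simulators
#'   (same units as `amplitude`); must be >= 0.
#'
#' @return An object of class `ground_truth_rhythm` (a named list).
#' @examples
#' truth <- ground_truth_rhythm(amplitude = 2, period = 24, equilibrium = 10)
#' rhythm_value(truth, t = c(16, 28, 40), t0 = 16)
#' @export
ground_truth_rhythm <- function(amplitude, ac_coef = 0, period = 24,
                                phase = 0, equilibrium = 0,
                                trend_slope = 0, noise_sd = 0) {
  vals <- c(amplitude = amplitude, ac_coef = ac_coef, period = period,
            phase = phase, equilibrium = equilibrium,
            trend_slope = trend_slope, noise_sd = noise_sd)
  if (!all(is.finite(vals))) {
    abort("all rhythm parameters must be finite numbers")
  }
  if (period <= 0) abort("`period` must be > 0")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  structure(as.list(vals), class = "ground_truth_rhythm")
}

#' Sampling design of a time-course experiment
#'
#' Describes when samples are taken (hours post serum shock) and how many
#' replicates and cells per image a simulated experiment carries. The default
#' reproduces the phagocytosis assay design: sampling every 4 h for 24 h
#' starting 16 h post shock (PS16, PS20, ..., PS40) in triplicate.
#'
#' @param start First sampling time, hours post shock (PS).
#' @param interval Sampling interval in hours; must be > 0.
#' @param span Total sampled span in hours; must be >= `interval`.
#' @param replicates Replicates per timepoint; must be >= 1.
#' @param cells_per_image Cells rendered per simulated image.
#' @param seed Integer seed for all randomness downstream of this design.
#'
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(start = 16, interval = 4, span = 24,
                              replicates = 3, cells_per_image = 20,
                              seed = 1L) {
  if (interval <= 0) abort("`interval` must be > 0")
  if (span < interval) abort("`span` must be >= `interval`")
  if (replicates < 1) abort("`replicates` must be >= 1")
  structure(
    list(start = start, interval = interval, span = span,
         replicates = as.integer(replicates),
         cells_per_image = as.integer(cells_per_image),
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Sampling times of a design
#'
#' @param design An [experiment_design()].
#' @return Numeric vector of timepoints in PS hours (inclusive of both ends).
#' @export
design_timepoints <- function(design) {
  seq(design$start, design$start + design$span, by = design$interval)
}

#' Evaluate the noiseless oscillator
#'
#' Computes `C + b(t - t0) + A exp(-gamma (t - t0)) cos(2 pi (t - t0)/tau + phi)`
#' for each `t`. This is the analytic form every simulator and the rhythm
#' fitter share.
#'
#' @param truth A [ground_truth_rhythm()].
#' @param t Time(s) in hours (vectorized).
#' @param t0 Reference time (hours); phase and decay are anchored here.
#' @return Numeric vector, `length(t)` noiseless values.
#' @export
rhythm_value <- function(truth, t, t0 = 0) {
  stopifnot(inherits(truth, "ground_truth_rhythm"))
  if (!all(is.finite(t)) || !is.finite(t0)) abort("times must be finite")
  dt <- t - t0
  truth$equilibrium + truth$trend_slope * dt +
    truth$amplitude * exp(-truth$ac_coef * dt) *
      cos(2 * pi * dt / truth$period + truth$phase)
}

#' Simulate a replicate-resolved rhythm series
#'
#' Draws `replicates` independent noisy observations of the oscillator at each
#' design timepoint. Noise is additive Gaussian with sd `truth$noise_sd`.
#'
#' @param truth A [ground_truth_rhythm()].
#' @param design An [experiment_design()].
#' @param id Series identifier carried into the output.
#' @param seed Seed; defaults to `design$seed`.
#' @param clamp_zero If `TRUE`, negative draws are truncated at 0 (used for
#'   concentrations) and the truncation count is attached as attribute
#'   `"n_clamped"`.
#' @return A tibble with columns `id`, `time_ps`, `replicate`, `value`.
#' @export
simulate_rhythm_series <- function(truth, design, id = "series",
                                   seed = design$seed, clamp_zero = FALSE) {
  tp <- design_timepoints(design)
  grid <- tidyr::expand_grid(time_ps = tp,
                             replicate = seq_len(design$replicates))
  vals <- withr::with_seed(seed, {
    mu <- rhythm_value(truth, grid$time_ps, t0 = design$start)
    mu + rnorm(nrow(grid), 0, truth$noise_sd)
  })
  n_clamped <- 0L
  if (clamp_zero) {
    n_clamped <- sum(vals < 0)
    vals <- pmax(vals, 0)
  }
  out <- tibble(id = id, time_ps = grid$time_ps,
                replicate = grid$replicate, value = vals)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Simulate a dense luminescence reference trace
#'
#' Emulates a lumicycle recording of clock-gene reporter expression from
#' synchronized cells: a dense (default 0.5 h step) oscillator trace used to
#' anchor circadian phase. Noise sd comes from `truth$noise_sd` (0 gives the
#' noiseless trace).
#'
#' @inheritParams simulate_rhythm_series
#' @param step Sampling step in hours, at most 0.5.
#' @return A tibble with columns `id`, `time_ps`, `replicate` (always 1),
#'   `value`.
#' @export
simulate_luminescence_trace <- function(truth, design, step = 0.5,
                                        id = "luminescence",
                                        seed = design$seed) {
  if (step > 0.5) abort("`step` must be <= 0.5 h for a dense trace")
  tp <- seq(design$start, design$start + design$span, by = step)
  vals <- withr::with_seed(seed, {
    rhythm_value(truth, tp, t0 = design$start) +
      rnorm(length(tp), 0, truth$noise_sd)
  })
  tibble(id = id, time_ps = tp, replicate = 1L, value = vals)
}
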