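#' Circadian rhythm classification criteria
#'
#' Gates a fitted oscillator must clear to be called circadian: a period
#' within `[period_min, period_max]` hours, an amplitude-change coefficient of
#' at most `ac_max` in magnitude (inclusive), and raw, BH-adjusted and
#' BY-adjusted fit p values all below `alpha`.
#'
#' @param period_min,period_max Period window in hours (defaults 18 and 30).
#' @param ac_max Maximum `|gamma|` in 1/h (default 0.15).
#' @param alpha Significance level applied to the raw and adjusted p values
#'   (default 0.05).
#' @return An object of class `rhythm_criteria`.
#' @export
rhythm_criteria <- function(period_min = 18, period_max = 30,
                            ac_max = 0.15, alpha = 0.05) {
  if (period_min <= 0 || period_min >= period_max) {
    abort("need 0 < period_min < period_max")
  }
  if (ac_max < 0) abort("`ac_max` must be >= 0")
  structure(list(period_min = period_min, period_max = period_max,
                 ac_max = ac_max, alpha = alpha),
            class = "rhythm_criteria")
}

#' Detrend and smooth a rhythm series
#'
#' Removes a least-squares line fitted over all observation points, then
#' (optionally) smooths by shifting each timepoint's replicate mean to the
#' centred weighted moving average with weights (1, 2, 1)/4 over adjacent
#' timepoint means; endpoints use the available neighbours with weights
#' renormalized. Replicate deviations around their timepoint mean are
#' preserved, so replicate-resolved fitting is still possible afterwards.
#'
#' @param data Data frame with columns `time_ps`, `replicate`, `value`.
#' @param detrend,smooth Logical switches (both default `TRUE`, the free-run
#'   convention used throughout the package).
#' @return A tibble like `data` with `value` replaced by the preprocessed
#'   values, plus attributes `trend` (named numeric: `intercept`, `slope` of
#'   the removed line; both 0 when `detrend = FALSE`) and `smoothed`.
#' @export
preprocess_series <- function(data, detrend = TRUE, smooth = TRUE) {
  data <- as_tibble(data)
  stopifnot(all(c("time_ps", "replicate", "value") %in% names(data)))
  if (length(unique(data$time_ps)) < 3) {
    abort("need >= 3 distinct timepoints to preprocess")
  }
  trend <- c(intercept = 0, slope = 0)
  if (detrend) {
    fit <- lm(value ~ time_ps, data = data)
    trend <- setNames(coef(fit), c("intercept", "slope"))
    data$value <- data$value - (trend[1] + trend[2] * data$time_ps)
  }
  if (smooth) {
    tp <- sort(unique(data$time_ps))
    m <- vapply(tp, function(t) mean(data$value[data$time_ps == t]),
                numeric(1))
    sm <- smooth_121(m)
    shift <- setNames(sm - m, tp)
    data$value <- unname(data$value + shift[as.character(data$time_ps)])
  }
  attr(data, "trend") <- trend
  attr(data, "smoothed") <- smooth
  data
}

# (1,2,1)/4 centred moving average; endpoints renormalize over available
# neighbours: (2,1)/3 and (1,2)/3.
smooth_121 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  out <- x
  out[1] <- (2 * x[1] + x[2]) / 3
  out[n] <- (x[n - 1] + 2 * x[n]) / 3
  if (n > 2) {
    i <- 2:(n - 1)
    out[i] <- (x[i - 1] + 2 * x[i] + x[i + 1]) / 4
  }
  out
}

eho_model <- function(par, dt) {
  par["C"] + par["A"] * exp(-par["gamma"] * dt) *
    cos(2 * pi * dt / par["tau"] + par["phi"])
}

#' Fit the extended-harmonic-oscillator model
#'
#' Minimizes the sum of squared errors of
#' `y(t) = A exp(-gamma (t - t0)) cos(2 pi (t - t0)/tau + phi) + C`
#' over every observation point by Levenberg-Marquardt least squares from a
#' multi-start grid: periods 18-30 h in steps of 2, phases
#' {0, pi/2, pi, 3 pi/2}, amplitude-change coefficients {-0.1, 0, 0.1}, with
#' `A0 = (max - min)/2` and `C0 = mean(y)`. A constant-model start (`A = 0`)
#' is always included, so the returned SSE never exceeds the best constant
#' model's. The period is unconstrained during optimization (free run);
#' classification gates are applied afterwards by [classify_rhythm()].
#' Negative fitted amplitudes are normalized away by a half-period phase
#' flip and the phase is reduced to `[0, 2 pi)`.
#'
#' @param data Data frame with columns `time_ps`, `replicate`, `value`.
#' @param criteria A [rhythm_criteria()].
#' @param collapse_replicates If `TRUE`, replicates are collapsed to
#'   timepoint means before fitting (the phagocytosis convention); if
#'   `FALSE` (default) every observation is weighted equally (the
#'   proteoglycan convention).
#' @param detrend,smooth Passed to [preprocess_series()]; defaults `FALSE`
#'   here so the fitter can be used standalone on already-preprocessed data.
#' @param pvalue_method `"kendall"` (default) or `"ftest"`, see
#'   [rhythm_pvalue()].
#' @param id Identifier stored in the fit.
#' @return An object of class `eho_fit`: parameters (`amplitude`, `ac_coef`,
#'   `period`, `phase`, `equilibrium`), removed `trend`, `sse`,
#'   `sse_constant`, the fit p value `p` (adjusted values `p_bh`, `p_by`
#'   equal `p` until a catalog-level adjustment overwrites them), zenith and
#'   nadir times, convergence flag, the observation table, `t0` and the
#'   criteria used.
#' @export
fit_eho <- function(data, criteria = rhythm_criteria(),
                    collapse_replicates = FALSE,
                    detrend = FALSE, smooth = FALSE,
                    pvalue_method = c("kendall", "ftest"),
                    id = "series") {
  pvalue_method <- match.arg(pvalue_method)
  data <- as_tibble(data)
  stopifnot(all(c("time_ps", "replicate", "value") %in% names(data)))
  if (!all(is.finite(data$value))) abort("series values must be finite")
  if (length(unique(data$time_ps)) < 6) {
    abort("need >= 6 distinct timepoints to fit the oscillator")
  }
  prep <- preprocess_series(data, detrend = detrend, smooth = smooth)
  trend <- attr(prep, "trend")
  obs <- if (collapse_replicates) {
    prep |>
      group_by(.data$time_ps) |>
      summarise(value = mean(.data$value), .groups = "drop")
  } else {
    prep
  }
  t0 <- min(obs$time_ps)
  dt <- obs$time_ps - t0
  y <- obs$value

  a0 <- (max(y) - min(y)) / 2
  c0 <- mean(y)
  starts <- tidyr::expand_grid(tau = seq(18, 30, by = 2),
                               phi = c(0, pi / 2, pi, 3 * pi / 2),
                               gamma = c(-0.1, 0, 0.1)) |>
    mutate(A = a0, C = c0)
  starts <- bind_rows(starts,
                      tibble(tau = 24, phi = 0, gamma = 0, A = 0, C = c0))

  resid_fn <- function(par) y - eho_model(par, dt)
  ctrl <- minpack.lm::nls.lm.control(ptol = 1e-8, maxiter = 200,
                                     maxfev = 2000)
  results <- list()
  for (i in seq_len(nrow(starts))) {
    par0 <- c(A = starts$A[i], gamma = starts$gamma[i], tau = starts$tau[i],
              phi = starts$phi[i], C = starts$C[i])
    res <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = par0, fn = resid_fn, control = ctrl)
      ),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$deviance)) next
    results <- c(results, list(res))
  }
  n_converged <- length(results)
  # Sampling every few hours aliases the period: a short-period oscillator
  # can pass through exactly the same gridpoint values as a circadian one,
  # tying the SSE. Among (near-)tied minima, prefer a period inside the
  # criteria band, the convention rhythm-detection tools adopt via their
  # period search range.
  best <- NULL
  if (n_converged > 0) {
    dev <- vapply(results, `[[`, numeric(1), "deviance")
    dmin <- min(dev)
    tied <- which(dev <= dmin + 1e-4 * max(dmin, 1e-12))
    in_band <- vapply(results[tied], function(r) {
      tau <- abs(unname(r$par["tau"]))
      tau >= criteria$period_min && tau <= criteria$period_max
    }, logical(1))
    pick <- if (any(in_band)) {
      tied[in_band][which.min(dev[tied[in_band]])]
    } else {
      which.min(dev)
    }
    best <- results[[pick]]
  }
  sse_constant <- sum((y - mean(y))^2)

  if (is.null(best)) {
    par <- c(A = 0, gamma = 0, tau = 24, phi = 0, C = c0)
    sse <- sse_constant
    converged <- FALSE
  } else {
    par <- best$par
    sse <- best$deviance
    converged <- TRUE
    if (sse > sse_constant) {
      par <- c(A = 0, gamma = 0, tau = 24, phi = 0, C = c0)
      sse <- sse_constant
    }
  }
  # canonical form: tau > 0, A >= 0, phi in [0, 2 pi)
  if (par["tau"] < 0) {
    par["tau"] <- -par["tau"]
    par["phi"] <- -par["phi"]
  }
  if (par["A"] < 0) {
    par["A"] <- -par["A"]
    par["phi"] <- par["phi"] + pi
  }
  par["phi"] <- par["phi"] %% (2 * pi)

  fitted_vals <- eho_model(par, dt)
  p <- rhythm_pvalue(fitted_vals, y, method = pvalue_method,
                     n_par = 5L, sse = sse, sse0 = sse_constant)

  fit <- structure(
    list(id = id,
         amplitude = unname(par["A"]), ac_coef = unname(par["gamma"]),
         period = unname(par["tau"]), phase = unname(par["phi"]),
         equilibrium = unname(par["C"]),
         trend_intercept = unname(trend[1]), trend_slope = unname(trend[2]),
         sse = sse, sse_constant = sse_constant,
         p = p, p_bh = p, p_by = p,
         n_obs = length(y), n_timepoints = length(unique(obs$time_ps)),
         t0 = t0, window = range(obs$time_ps),
         observations = tibble(time_ps = obs$time_ps, value = y,
                               fitted = fitted_vals),
         converged = converged, n_starts_converged = n_converged,
         collapse_replicates = collapse_replicates,
         smoothed = smooth, detrended = detrend,
         pvalue_method = pvalue_method,
         criteria = criteria),
    class = "eho_fit"
  )
  zn <- zenith_nadir(fit)
  fit$zenith_ps <- zn$zenith_ps
  fit$nadir_ps <- zn$nadir_ps
  cl <- classify_rhythm(fit, criteria)
  fit$circadian <- cl$circadian
  fit$reasons <- cl$reasons
  fit
}

#' Predict from a fitted oscillator
#'
#' Evaluates the fitted damped cosine (without the removed trend) at new
#' times.
#'
#' @param fit An [fit_eho()] result.
#' @param t Times in PS hours.
#' @return Numeric vector of fitted values.
#' @export
eho_predict <- function(fit, t) {
  stopifnot(inherits(fit, "eho_fit"))
  par <- c(A = fit$amplitude, gamma = fit$ac_coef, tau = fit$period,
           phi = fit$phase, C = fit$equilibrium)
  eho_model(par, t - fit$t0)
}

#' Goodness-of-fit p value for an oscillator fit
#'
#' Default method: a one-sided Kendall rank-correlation test of positive
#' association between fitted values and observations across all points
#' (exact tail where ties permit, normal approximation otherwise). Degenerate
#' inputs (constant fitted values or observations, fewer than 4 points)
#' return `p = 1`. The alternative `"ftest"` compares the oscillator against
#' the constant model with an F statistic on (4, n - 5) degrees of freedom.
#'
#' @param fitted,observed Numeric vectors of equal length.
#' @param method `"kendall"` or `"ftest"`.
#' @param n_par Number of oscillator parameters (used by the F test).
#' @param sse,sse0 Oscillator and constant-model SSE (used by the F test).
#' @return p value in `[0, 1]`.
#' @export
rhythm_pvalue <- function(fitted, observed,
                          method = c("kendall", "ftest"),
                          n_par = 5L, sse = NULL, sse0 = NULL) {
  method <- match.arg(method)
  n <- length(observed)
  if (method == "ftest") {
    if (is.null(sse) || is.null(sse0)) {
      sse <- sum((observed - fitted)^2)
      sse0 <- sum((observed - mean(observed))^2)
    }
    df2 <- n - n_par
    if (df2 <= 0 || sse <= 0) return(if (sse0 > sse) 0 else 1)
    f <- ((sse0 - sse) / (n_par - 1)) / (sse / df2)
    return(stats::pf(f, n_par - 1, df2, lower.tail = FALSE))
  }
  if (n < 4) return(1)
  if (sd(fitted) == 0 || sd(observed) == 0) return(1)
  ht <- suppressWarnings(
    cor.test(fitted, observed, method = "kendall", alternative = "greater")
  )
  min(max(ht$p.value, 0), 1)
}

#' Benjamini-Hochberg and Benjamini-Yekutieli adjustment
#'
#' Standard step-up adjustments applied across a catalog of raw p values;
#' BY additionally multiplies by `c(m) = sum_{k=1}^{m} 1/k` to stay valid
#' under arbitrary dependence.
#'
#' @param p Numeric vector of raw p values in `[0, 1]`.
#' @return A tibble with columns `p`, `p_bh`, `p_by`.
#' @export
adjust_pvalues <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must be in [0, 1]")
  tibble(p = p, p_bh = p.adjust(p, "BH"), p_by = p.adjust(p, "BY"))
}

#' Classify a fit as circadian or not
#'
#' Applies the rhythmicity gates: period within the criteria window,
#' `|ac_coef|` at most the bound (inclusive), and raw, BH- and BY-adjusted
#' p values all below `alpha`. Every failed gate is named in the reason
#' codes. A pure function of the fit parameters, p values and criteria.
#'
#' @param fit An `eho_fit` (with `p_bh`/`p_by` set by a catalog-level
#'   adjustment; for a lone fit they equal the raw p).
#' @param criteria A [rhythm_criteria()]; defaults to the criteria stored in
#'   the fit.
#' @return A list with `circadian` (logical) and `reasons` (character vector
#'   of failed gates, empty when circadian).
#' @export
classify_rhythm <- function(fit, criteria = NULL) {
  stopifnot(inherits(fit, "eho_fit"))
  criteria <- criteria %||% fit$criteria
  gates <- c(
    period = fit$period >= criteria$period_min &&
      fit$period <= criteria$period_max,
    ac_coefficient = abs(fit$ac_coef) <= criteria$ac_max,
    p_value = fit$p < criteria$alpha,
    p_bh = fit$p_bh < criteria$alpha,
    p_by = fit$p_by < criteria$alpha
  )
  list(circadian = all(gates), reasons = names(gates)[!gates])
}

#' Zenith and nadir of a fitted oscillator
#'
#' Locates the maximum and minimum of the fitted damped cosine (trend
#' excluded) on a dense 0.01 h grid over the sampled window. An extremum
#' landing on a window boundary is flagged `clipped`; a zero-amplitude fit
#' has no defined extrema and returns `NA` with `undefined = TRUE`.
#'
#' @param fit An `eho_fit`.
#' @param window Length-2 numeric window in PS hours; defaults to the fitted
#'   window.
#' @return A list: `zenith_ps`, `nadir_ps`, `zenith_ct`, `nadir_ct`,
#'   `clipped`, `undefined`.
#' @export
zenith_nadir <- function(fit, window = NULL) {
  stopifnot(inherits(fit, "eho_fit"))
  window <- window %||% fit$window
  if (fit$amplitude == 0) {
    return(list(zenith_ps = NA_real_, nadir_ps = NA_real_,
                zenith_ct = NA_real_, nadir_ct = NA_real_,
                clipped = FALSE, undefined = TRUE))
  }
  grid <- seq(window[1], window[2], by = 0.01)
  yhat <- eho_predict(fit, grid)
  zen <- grid[which.max(yhat)]
  nad <- grid[which.min(yhat)]
  clipped <- any(c(zen, nad) %in% window)
  list(zenith_ps = zen, nadir_ps = nad,
       zenith_ct = time_convert(zen, "PS", "CT"),
       nadir_ct = time_convert(nad, "PS", "CT"),
       clipped = clipped, undefined = FALSE)
}

#' Convert between time bases
#'
#' Affine conversions among the three time bases used in the study:
#' `index` (sample number in chronological order), `PS` (hours post serum
#' shock; index 0 is PS16) and `CT` (circadian time anchored to the reference
#' PER2 zenith; PS20 is CT8, so CT = PS - 12). Round trips are exact.
#'
#' @param value Numeric time value(s).
#' @param from,to Bases: `"index"`, `"PS"` or `"CT"`.
#' @param index_offset PS hours of sample index 0 (default 16).
#' @param ct_offset Hours subtracted from PS to obtain CT (default 12).
#' @return Converted numeric value(s).
#' @export
time_convert <- function(value, from, to, index_offset = 16, ct_offset = 12) {
  bases <- c("index", "PS", "CT")
  if (!from %in% bases || !to %in% bases) {
    abort("time bases must be \"index\", \"PS\" or \"CT\"")
  }
  ps <- switch(from,
    index = value + index_offset,
    PS = value,
    CT = value + ct_offset
  )
  switch(to,
    index = ps - index_offset,
    PS = ps,
    CT = ps - ct_offset
  )
}
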