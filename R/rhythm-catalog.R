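#' Fit rhythms across a catalog of series
#'
#' Fits the extended harmonic oscillator to every series in a long table,
#' adjusts the fit p values across the whole catalog (BH and BY), and
#' classifies each series against the criteria. Multiple-testing adjustment
#' is catalog-level: verdicts depend on which series are fitted together.
#'
#' @param data Data frame with columns `id`, `time_ps`, `replicate`, `value`.
#' @param criteria A [rhythm_criteria()].
#' @param collapse_replicates,detrend,smooth,pvalue_method Passed to
#'   [fit_eho()].
#' @return A tibble with one row per series: the fitted parameters, `sse`,
#'   `p`, `p_bh`, `p_by`, `circadian`, `reasons` (comma-separated failed
#'   gates), zenith/nadir in PS and CT, `converged`, and a list-column `fit`
#'   holding each updated `eho_fit`.
#' @export
fit_rhythms <- function(data, criteria = rhythm_criteria(),
                        collapse_replicates = FALSE,
                        detrend = TRUE, smooth = TRUE,
                        pvalue_method = "kendall") {
  data <- as_tibble(data)
  stopifnot(all(c("id", "time_ps", "replicate", "value") %in% names(data)))
  ids <- unique(data$id)
  fits <- purrr::map(ids, function(sid) {
    fit_eho(filter(data, .data$id == sid), criteria = criteria,
            collapse_replicates = collapse_replicates,
            detrend = detrend, smooth = smooth,
            pvalue_method = pvalue_method, id = sid)
  })
  adj <- adjust_pvalues(vapply(fits, `[[`, numeric(1), "p"))
  fits <- purrr::imap(fits, function(f, i) {
    f$p_bh <- adj$p_bh[i]
    f$p_by <- adj$p_by[i]
    cl <- classify_rhythm(f, criteria)
    f$circadian <- cl$circadian
    f$reasons <- cl$reasons
    f
  })
  purrr::map(fits, tidy_eho_row) |>
    bind_rows() |>
    mutate(fit = fits)
}

tidy_eho_row <- function(fit) {
  tibble(
    id = fit$id,
    amplitude = fit$amplitude, ac_coef = fit$ac_coef, period = fit$period,
    phase = fit$phase, equilibrium = fit$equilibrium,
    trend_slope = fit$trend_slope,
    sse = fit$sse, p = fit$p, p_bh = fit$p_bh, p_by = fit$p_by,
    circadian = fit$circadian,
    reasons = paste(fit$reasons, collapse = ","),
    zenith_ps = fit$zenith_ps, nadir_ps = fit$nadir_ps,
    zenith_ct = time_convert(fit$zenith_ps, "PS", "CT"),
    nadir_ct = time_convert(fit$nadir_ps, "PS", "CT"),
    n_obs = fit$n_obs, converged = fit$converged
  )
}

#' @export
print.eho_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Extended harmonic oscillator fit: %s\n",
           "  A = %.4g, gamma = %.4g /h, period = %.4g h, ",
           "phase = %.4g rad, C = %.4g\n",
           "  SSE = %.4g (constant model %.4g), p = %.3g ",
           "(BH %.3g, BY %.3g)\n",
           "  zenith PS%.1f (CT%.1f), nadir PS%.1f (CT%.1f)\n",
           "  circadian: %s%s\n"),
    x$id, x$amplitude, x$ac_coef, x$period, x$phase, x$equilibrium,
    x$sse, x$sse_constant, x$p, x$p_bh, x$p_by,
    x$zenith_ps, time_convert(x$zenith_ps, "PS", "CT"),
    x$nadir_ps, time_convert(x$nadir_ps, "PS", "CT"),
    ifelse(x$circadian, "yes", "no"),
    if (length(x$reasons)) paste0(" (failed: ",
                                  paste(x$reasons, collapse = ", "), ")")
    else ""
  ))
  invisible(x)
}

#' Tidy an oscillator fit
#'
#' @param x An `eho_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`term`, `estimate`).
#' @export
tidy.eho_fit <- function(x, ...) {
  tibble(
    term = c("amplitude", "ac_coef", "period", "phase", "equilibrium"),
    estimate = c(x$amplitude, x$ac_coef, x$period, x$phase, x$equilibrium)
  )
}

#' One-row summary of an oscillator fit
#'
#' @param x An `eho_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit statistics, verdict and extrema.
#' @export
glance.eho_fit <- function(x, ...) {
  select(tidy_eho_row(x), -"id")
}

#' Observations with fitted values and residuals
#'
#' @param x An `eho_fit`.
#' @param ... Unused.
#' @return The observation tibble with `.fitted` and `.resid` columns.
#' @export
augment.eho_fit <- function(x, ...) {
  x$observations |>
    mutate(.fitted = .data$fitted, .resid = .data$value - .data$fitted) |>
    select(-"fitted")
}

#' Plot an oscillator fit
#'
#' Observations (points) with the fitted damped cosine evaluated on a dense
#' grid, in PS hours.
#'
#' @param object An `eho_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eho_fit <- function(object, ...) {
  grid <- seq(object$window[1], object$window[2], by = 0.1)
  curve <- tibble(time_ps = grid, value = eho_predict(object, grid))
  ggplot2::ggplot(object$observations,
                  ggplot2::aes(x = .data$time_ps, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = curve, colour = "#7570b3") +
    ggplot2::labs(
      x = "Time (h post shock)", y = "Value",
      title = sprintf("%s: period %.1f h, p = %.2g%s", object$id,
                      object$period, object$p,
                      ifelse(object$circadian, " (circadian)", ""))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Violin plot of per-cell intensities over time
#'
#' The standard presentation of phagocytosis data: one violin of logged
#' per-cell intensities per timepoint with the timepoint mean marked, and
#' optionally the fitted oscillator overlaid.
#'
#' @param data Preprocessed table with `time_ps` and `log10_intensity`.
#' @param fit Optional `eho_fit` to overlay (fitted on collapsed means).
#' @return A ggplot object.
#' @export
plot_phagocytosis <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = factor(.data$time_ps),
                                          y = .data$log10_intensity)) +
    ggplot2::geom_violin(colour = "#7570b3", fill = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.2, size = 0.4,
                         colour = "grey40") +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          shape = 18, size = 3) +
    ggplot2::labs(x = "Time (h post shock)",
                  y = "log10 mean cell fluorescence") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    grid <- seq(fit$window[1], fit$window[2], by = 0.1)
    tps <- sort(unique(data$time_ps))
    curve <- tibble(
      xpos = 1 + (grid - tps[1]) / diff(range(tps)) * (length(tps) - 1),
      value = eho_predict(fit, grid)
    )
    p <- p + ggplot2::geom_line(
      data = curve, ggplot2::aes(x = .data$xpos, y = .data$value),
      linetype = "dashed", colour = "#7570b3"
    )
  }
  p
}
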