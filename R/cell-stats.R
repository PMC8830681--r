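#' Preprocess per-cell intensities
#'
#' Applies the study's filtering in a single pass: (1) values at or below the
#' background signal are below threshold and removed; (2) survivors are log10
#' transformed; (3) within each timepoint, values outside the Tukey fences
#' `[Q1 - k IQR, Q3 + k IQR]` of that timepoint's logged values are removed
#' (fences computed once, not iterated; quantiles by linear interpolation).
#' A timepoint left with fewer than 3 values after step 1 is flagged and the
#' IQR step is skipped there.
#'
#' @param data Data frame with columns `time_ps`, `replicate` and the raw
#'   intensity column named by `value`.
#' @param background_signal Scalar threshold; raw values <= this are removed.
#' @param iqr_multiplier Tukey fence multiplier `k` (default 1.5).
#' @param value Name of the raw intensity column (default
#'   `"corrected_mean"`).
#' @return A tibble of the retained rows with `log10_intensity` added, plus
#'   attributes `removed` (tibble of removed rows, each flagged with exactly
#'   one of `below_threshold_removed` / `iqr_removed`) and `skipped_iqr`
#'   (timepoints where the IQR step was skipped).
#' @export
preprocess_intensities <- function(data, background_signal,
                                   iqr_multiplier = 1.5,
                                   value = "corrected_mean") {
  data <- as_tibble(data)
  stopifnot(value %in% names(data), "time_ps" %in% names(data))
  raw <- data[[value]]
  below <- raw <= background_signal
  removed_below <- data[below, , drop = FALSE] |>
    mutate(below_threshold_removed = TRUE, iqr_removed = FALSE)
  kept <- data[!below, , drop = FALSE] |>
    mutate(log10_intensity = log10(.data[[value]]))

  skipped <- numeric()
  keep_flags <- rep(TRUE, nrow(kept))
  for (tp in unique(kept$time_ps)) {
    sel <- which(kept$time_ps == tp)
    v <- kept$log10_intensity[sel]
    if (length(v) < 3) {
      skipped <- c(skipped, tp)
      next
    }
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- c(q[1] - iqr_multiplier * diff(q),
               q[2] + iqr_multiplier * diff(q))
    keep_flags[sel] <- v >= fence[1] & v <= fence[2]
  }
  removed_iqr <- kept[!keep_flags, , drop = FALSE] |>
    mutate(below_threshold_removed = FALSE, iqr_removed = TRUE)
  out <- kept[keep_flags, , drop = FALSE]
  attr(out, "removed") <- bind_rows(removed_below, removed_iqr)
  attr(out, "skipped_iqr") <- skipped
  out
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom and a
#' two-sided p value. The degenerate case of two zero-variance samples is
#' handled explicitly: equal means give `t = 0, p = 1`; unequal means give
#' `p = 0` and `degenerate = TRUE`.
#'
#' @param x,y Numeric samples with at least 2 finite values each.
#' @return A one-row tibble: `t`, `df`, `p`, `n1`, `n2`, `degenerate`.
#' @export
welch_test <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) abort("need n >= 2 in each group")
  if (var(x) == 0 && var(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                  df = NA_real_, p = if (same) 1 else 0,
                  n1 = length(x), n2 = length(y), degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, n1 = length(x), n2 = length(y),
         degenerate = FALSE)
}

#' Hedges' g standardized effect size
#'
#' Cohen's d on the pooled standard deviation, multiplied by the small-sample
#' correction `J = 1 - 3 / (4 (n1 + n2) - 9)`. The effect class follows the
#' conventional bands on `|g|`: above 0.2 small, above 0.5 medium, above 0.8
#' large, otherwise negligible. Appropriate when the two groups have unequal
#' sizes.
#'
#' @param x,y Numeric samples with at least 2 finite values each and positive
#'   pooled variance.
#' @return A one-row tibble: `g` (signed), `effect_class`, `n1`, `n2`.
#' @export
hedges_g <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("need n >= 2 in each group")
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("pooled variance is zero: Hedges' g is undefined")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  g <- d * (1 - 3 / (4 * (n1 + n2) - 9))
  tibble(g = g, effect_class = effect_class(g), n1 = n1, n2 = n2)
}

effect_class <- function(g) {
  a <- abs(g)
  dplyr::case_when(
    a > 0.8 ~ "large",
    a > 0.5 ~ "medium",
    a > 0.2 ~ "small",
    TRUE ~ "negligible"
  )
}

#' Joint significance decision
#'
#' A contrast is called significant only when the p value clears `alpha` AND
#' the effect size is at least `g_min` in magnitude: a large effect confirms a
#' small p, a small effect negates it.
#'
#' @param p Two-sided p value in `[0, 1]`.
#' @param g Signed Hedges' g.
#' @param alpha Significance level (default 0.05).
#' @param g_min Minimum `|g|` (default 0.5; stricter contrasts use 2.0).
#' @return Logical verdict.
#' @export
joint_decision <- function(p, g, alpha = 0.05, g_min = 0.5) {
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1]")
  p < alpha & abs(g) >= g_min
}

#' Compare two groups of cells
#'
#' Data-frame-first wrapper combining [welch_test()], [hedges_g()] and
#' [joint_decision()] for one two-group contrast.
#'
#' @param data Data frame of preprocessed measurements.
#' @param value Name of the value column (default `"log10_intensity"`).
#' @param group Name of the grouping column.
#' @param groups Length-2 character vector selecting (in order) the two
#'   levels to contrast; defaults to the first two levels encountered.
#' @param alpha,g_min Gates passed to [joint_decision()].
#' @return A one-row tibble: `group1`, `group2`, `n1`, `n2`, `t`, `df`, `p`,
#'   `g`, `effect_class`, `significant`, `alpha`, `g_min`.
#' @export
compare_groups <- function(data, value = "log10_intensity", group,
                           groups = NULL, alpha = 0.05, g_min = 0.5) {
  data <- as_tibble(data)
  stopifnot(value %in% names(data), group %in% names(data))
  lev <- groups %||% unique(as.character(data[[group]]))[1:2]
  x <- data[[value]][data[[group]] == lev[1]]
  y <- data[[value]][data[[group]] == lev[2]]
  wt <- welch_test(x, y)
  hg <- hedges_g(x, y)
  tibble(group1 = lev[1], group2 = lev[2], n1 = wt$n1, n2 = wt$n2,
         t = wt$t, df = wt$df, p = wt$p, g = hg$g,
         effect_class = hg$effect_class,
         significant = joint_decision(wt$p, hg$g, alpha, g_min),
         alpha = alpha, g_min = g_min)
}

#' Per-timepoint summary of a measurement table
#'
#' Computes the mean of each replicate at each timepoint and then the
#' cross-replicate mean, retaining both: rhythm fitting of phagocytosis data
#' consumes the cross-replicate means while proteoglycan analysis keeps every
#' replicate.
#'
#' @param data Data frame with columns `time_ps`, `replicate` and the value
#'   column named by `value`.
#' @param value Name of the value column (default `"log10_intensity"`).
#' @return A list with `replicate_means` (tibble: `time_ps`, `replicate`,
#'   `mean`, `n`) and `timepoint_means` (tibble: `time_ps`, `mean`,
#'   `n_replicates`); timepoints with no retained values are absent and their
#'   ids are recorded in attribute `"empty_timepoints"` of the list.
#' @export
timepoint_summary <- function(data, value = "log10_intensity") {
  data <- as_tibble(data)
  stopifnot(all(c("time_ps", "replicate", value) %in% names(data)))
  rep_means <- data |>
    group_by(.data$time_ps, .data$replicate) |>
    summarise(mean = mean(.data[[value]]), n = dplyr::n(), .groups = "drop")
  tp_means <- rep_means |>
    group_by(.data$time_ps) |>
    summarise(mean = mean(.data$mean), n_replicates = dplyr::n(),
              .groups = "drop")
  out <- list(replicate_means = rep_means, timepoint_means = tp_means)
  attr(out, "empty_timepoints") <- setdiff(unique(data$time_ps),
                                           tp_means$time_ps)
  out
}
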