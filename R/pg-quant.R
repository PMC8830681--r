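#' Fit a cell-count standard curve
#'
#' Ordinary least squares line `fluorescence = slope * count + intercept`
#' through the points of a DNA-stain calibration series.
#'
#' @param data Data frame with columns `cell_count` and `fluorescence`
#'   (>= 3 points over >= 2 distinct counts).
#' @param dilution_factor Dilution applied to samples before reading; stored
#'   for back-calculation.
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `n`, `dilution_factor`, and the underlying `lm` fit.
#' @export
fit_standard_curve <- function(data, dilution_factor = 1) {
  data <- as_tibble(data)
  stopifnot(all(c("cell_count", "fluorescence") %in% names(data)))
  if (nrow(data) < 3) abort("need >= 3 standard-curve points")
  if (length(unique(data$cell_count)) < 2) {
    abort("need >= 2 distinct cell counts")
  }
  fit <- lm(fluorescence ~ cell_count, data = data)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((data$fluorescence - mean(data$fluorescence))^2)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = if (sst > 0) 1 - ssr / sst else 1,
         n = nrow(data), dilution_factor = dilution_factor, lm = fit),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "Standard curve: fluorescence = %.4g * cells + %.4g (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Tidy a standard curve
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`,
#'   `dilution_factor`.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
         n = x$n, dilution_factor = x$dilution_factor)
}

#' Back-calculate cell counts from fluorescence
#'
#' Inverts the standard curve: `count = dilution * (F - intercept) / slope`.
#' Negative back-calculated counts are clamped to 0 and flagged.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param fluorescence Numeric fluorescence reading(s).
#' @param dilution Dilution factor; defaults to the curve's.
#' @return Numeric cell count(s) with logical attribute `clamped` marking
#'   readings below the curve intercept.
#' @export
cells_from_fluorescence <- function(curve, fluorescence,
                                    dilution = curve$dilution_factor) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) abort("standard curve slope must be nonzero")
  count <- dilution * (fluorescence - curve$intercept) / curve$slope
  clamped <- count < 0
  structure(pmax(count, 0), clamped = clamped)
}

#' Normalize a raw amount to per-cell units
#'
#' @param raw_ng Raw amount(s) in ng per sample.
#' @param cell_count Cell count(s); non-positive counts yield `NA` and are
#'   flagged.
#' @return ng/cell value(s) with logical attribute `flagged` marking
#'   non-positive counts.
#' @export
normalize_per_cell <- function(raw_ng, cell_count) {
  bad <- !is.finite(cell_count) | cell_count <= 0
  out <- ifelse(bad, NA_real_, raw_ng / cell_count)
  structure(out, flagged = bad)
}

#' Normalize a disaccharide table
#'
#' Adds a `value` column in compartment-appropriate units: ng/cell for the
#' cell compartment (raw amount divided by the back-calculated cell count)
#' and ng/ml otherwise (raw amount divided by sample volume). Mixing the two
#' unit systems downstream is an error guarded by the `units` column.
#'
#' @param data Disaccharide table with columns `class`, `code`,
#'   `compartment`, `time_ps`, `replicate`, `raw_ng`, plus per-row
#'   `cyquant_fluorescence` and `dilution` for cell rows and
#'   `sample_volume_ml` for the others.
#' @param curve A [fit_standard_curve()] for the cell compartment (required
#'   when cell rows are present).
#' @return The table with `cell_count`, `value` and `units` columns added.
#' @export
normalize_disaccharides <- function(data, curve = NULL) {
  data <- as_tibble(data)
  check_sulfation_code(data$class, data$code)
  is_cell <- data$compartment == "cell"
  data$cell_count <- NA_real_
  data$value <- NA_real_
  data$units <- ifelse(is_cell, "ng/cell", "ng/ml")
  if (any(is_cell)) {
    if (is.null(curve)) abort("cell-compartment rows need a standard curve")
    stopifnot("cyquant_fluorescence" %in% names(data),
              "dilution" %in% names(data))
    counts <- cells_from_fluorescence(curve,
                                      data$cyquant_fluorescence[is_cell],
                                      data$dilution[is_cell])
    data$cell_count[is_cell] <- as.numeric(counts)
    data$value[is_cell] <- as.numeric(
      normalize_per_cell(data$raw_ng[is_cell], data$cell_count[is_cell]))
  }
  if (any(!is_cell)) {
    stopifnot("sample_volume_ml" %in% names(data))
    data$value[!is_cell] <- data$raw_ng[!is_cell] /
      data$sample_volume_ml[!is_cell]
  }
  data
}

#' Class totals per sample
#'
#' Sums normalized values over sulfation codes within each
#' (class, compartment, timepoint, replicate) sample, then attaches the
#' cross-replicate mean and sd per timepoint. Mixing units within one
#' class/compartment group is an error.
#'
#' @param data Normalized table with columns `class`, `code`, `compartment`,
#'   `time_ps`, `replicate`, `value`, `units`.
#' @return A tibble: `class`, `compartment`, `time_ps`, `replicate`, `total`,
#'   `units`, `mean_total`, `sd_total` (the last two constant within a
#'   timepoint).
#' @export
class_totals <- function(data) {
  data <- as_tibble(data)
  if (anyNA(data$value)) {
    warn("dropping rows with missing normalized values")
    data <- filter(data, !is.na(.data$value))
  }
  per_sample <- data |>
    group_by(.data$class, .data$compartment, .data$time_ps,
             .data$replicate) |>
    summarise(total = sum(.data$value),
              n_units = dplyr::n_distinct(.data$units),
              units = .data$units[1], .groups = "drop")
  if (any(per_sample$n_units > 1)) {
    abort("mixed units within one class/compartment sample")
  }
  per_sample |>
    select(-"n_units") |>
    group_by(.data$class, .data$compartment, .data$time_ps) |>
    mutate(mean_total = mean(.data$total),
           sd_total = stats::sd(.data$total)) |>
    ungroup()
}

#' Species-by-timepoint Z-score matrix
#'
#' For each species (class:code), computes cross-replicate timepoint means
#' and standardizes them within the species row: `z = (x - mean) / sd` with
#' the sample (n-1) sd. Constant rows have no spread and are returned as
#' zeros, flagged.
#'
#' @param data Normalized table with `class`, `code`, `time_ps`, `replicate`,
#'   `value`.
#' @return A tibble: `species`, `time_ps`, `z`, `flat` (TRUE for zero-sd
#'   rows). Use [tidyr::pivot_wider()] for the wide species x PS matrix.
#' @export
zscore_matrix <- function(data) {
  data <- as_tibble(data)
  means <- data |>
    group_by(species = paste(.data$class, .data$code, sep = ":"),
             .data$time_ps) |>
    summarise(mean = mean(.data$value), .groups = "drop")
  counts <- means |> dplyr::count(.data$species)
  if (any(counts$n < 2)) abort("each species needs >= 2 timepoints")
  means |>
    group_by(.data$species) |>
    mutate(flat = stats::sd(.data$mean) == 0,
           z = ifelse(.data$flat, 0,
                      (.data$mean - mean(.data$mean)) /
                        stats::sd(.data$mean))) |>
    ungroup() |>
    select("species", "time_ps", "z", "flat")
}

#' Rhythm verdicts for every disaccharide species
#'
#' Fits the oscillator to each species' replicate-resolved normalized series
#' (no replicate collapsing: every replicate enters the fit) and to each
#' class total, with BH/BY adjustment across everything fitted in the call.
#' Species with no detected signal (all-zero series) are excluded from
#' fitting, mirroring the convention of analysing only detected species.
#'
#' @param data Normalized table with `class`, `code`, `time_ps`, `replicate`,
#'   `value`.
#' @param criteria A [rhythm_criteria()].
#' @param include_totals Also fit the per-class totals (default `TRUE`).
#' @param detrend,smooth Passed to [fit_rhythms()].
#' @return The [fit_rhythms()] tibble, one row per fitted species/total.
#' @export
species_rhythms <- function(data, criteria = rhythm_criteria(),
                            include_totals = TRUE,
                            detrend = TRUE, smooth = TRUE) {
  data <- as_tibble(data)
  series <- data |>
    mutate(id = paste(.data$class, .data$code, sep = ":")) |>
    select("id", "time_ps", "replicate", "value")
  if (include_totals) {
    totals <- class_totals(data) |>
      mutate(id = paste0(.data$class, ":total")) |>
      select("id", "time_ps", "replicate", value = "total")
    series <- bind_rows(series, totals)
  }
  detected <- series |>
    group_by(.data$id) |>
    filter(any(.data$value > 0)) |>
    ungroup()
  fit_rhythms(detected, criteria = criteria, collapse_replicates = FALSE,
              detrend = detrend, smooth = smooth)
}

#' Z-score heatmap of disaccharide species over time
#'
#' @param zscores Output of [zscore_matrix()].
#' @return A ggplot tile heatmap (species rows, PS columns).
#' @export
plot_zscore_heatmap <- function(zscores) {
  ggplot2::ggplot(zscores,
                  ggplot2::aes(x = factor(.data$time_ps), y = .data$species,
                               fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "Time (h post shock)", y = NULL, fill = "Z-score") +
    ggplot2::theme_minimal()
}
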