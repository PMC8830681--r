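#' Segmentation configuration
#'
#' Parameters of the edge-detection segmentation used to pick out single cells
#' and clumps of up to `max_clump_size` cells. The default area window is
#' calibrated to the synthetic generator's discs (radius 10 px) and must be
#' recalibrated for real images.
#'
#' @param a_min,a_max Single-cell area range in px^2 (0 < a_min < a_max).
#' @param max_clump_size Largest clump kept, in cells (default 4).
#' @param edge_threshold Relative edge-strength threshold: edge pixels are
#'   those whose Sobel gradient magnitude exceeds `edge_threshold * max`.
#' @param close_radius Radius (px) of the disc brush used to close gaps in the
#'   edge ring before hole filling.
#' @param interior_erode Radius (px) by which the filled mask is eroded before
#'   intensity measurement, so object means are taken over interior pixels
#'   rather than the boundary band.
#' @param background_method Background estimator tag; only `"otsu"` is
#'   implemented.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(a_min = 150, a_max = 460,
                                max_clump_size = 4,
                                edge_threshold = 0.2,
                                close_radius = 1,
                                interior_erode = 2,
                                background_method = "otsu") {
  if (a_min <= 0 || a_min >= a_max) abort("need 0 < a_min < a_max")
  if (max_clump_size < 1) abort("`max_clump_size` must be >= 1")
  if (edge_threshold <= 0 || edge_threshold >= 1) {
    abort("`edge_threshold` must be in (0, 1)")
  }
  if (background_method != "otsu") abort("unknown `background_method`")
  structure(
    list(a_min = a_min, a_max = a_max,
         max_clump_size = as.integer(max_clump_size),
         edge_threshold = edge_threshold,
         close_radius = as.integer(close_radius),
         interior_erode = as.integer(interior_erode),
         background_method = background_method),
    class = "segmentation_config"
  )
}

#' Estimate the image background level
#'
#' Splits the intensity histogram with Otsu's bimodal threshold and returns
#' the mean of the sub-threshold (background) pixels. A constant image has no
#' foreground: its value is returned as-is and flagged via the
#' `"no_foreground"` attribute.
#'
#' @param image Numeric matrix of pixel intensities.
#' @return Background level (scalar) with logical attribute `no_foreground`.
#' @export
estimate_background <- function(image) {
  if (length(image) == 0) abort("`image` must be non-empty")
  if (!all(is.finite(image))) abort("`image` must be finite")
  rng <- range(image)
  if (diff(rng) == 0) {
    return(structure(rng[1], no_foreground = TRUE))
  }
  norm <- (image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  thr <- rng[1] + thr * diff(rng)
  structure(mean(image[image <= thr]), no_foreground = FALSE)
}

sobel_gradient <- function(image) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- EBImage::filter2(image, kx)
  gy <- EBImage::filter2(image, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Segment cell objects by edge detection
#'
#' Thresholds the Sobel gradient magnitude at `edge_threshold * max`, closes
#' small gaps in the edge ring, fills holes, and extracts connected
#' components. Components with area below `a_min` or above
#' `max_clump_size * a_max` are discarded; the clump size of a retained
#' component is the smallest `k` with area <= `k * a_max` (capped at
#' `max_clump_size`). Touching cells are measured as one clump, not split.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param cfg A [segmentation_config()].
#' @return A tibble with one row per retained object: `label`, `area_px2`,
#'   `clump_size`, `x`, `y` (0-based centroid) and list-columns `pixels`
#'   (linear indices of all member pixels) and `pixels_interior` (indices
#'   remaining after erosion, used for intensity measurement; falls back to
#'   `pixels` if erosion empties the object).
#' @export
segment_objects <- function(image, cfg = segmentation_config()) {
  stopifnot(inherits(cfg, "segmentation_config"))
  grad <- sobel_gradient(image)
  gmax <- max(grad)
  empty <- tibble(label = integer(), area_px2 = numeric(),
                  clump_size = integer(), x = numeric(), y = numeric(),
                  pixels = list(), pixels_interior = list())
  if (gmax == 0) return(empty)
  mask <- grad > cfg$edge_threshold * gmax
  storage.mode(mask) <- "integer"
  brush <- EBImage::makeBrush(2L * cfg$close_radius + 1L, "disc")
  mask <- EBImage::closing(mask, brush)
  filled <- EBImage::fillHull(mask)
  labels <- EBImage::bwlabel(filled)
  if (max(labels) == 0) return(empty)
  interior <- if (cfg$interior_erode > 0) {
    EBImage::erode(filled,
                   EBImage::makeBrush(2L * cfg$interior_erode + 1L, "disc"))
  } else {
    filled
  }

  idx_by_label <- split(seq_along(labels), as.vector(labels))
  idx_by_label <- idx_by_label[names(idx_by_label) != "0"]
  rows <- purrr::imap(idx_by_label, function(idx, lab) {
    area <- length(idx)
    if (area < cfg$a_min || area > cfg$max_clump_size * cfg$a_max) {
      return(NULL)
    }
    inner <- idx[interior[idx] > 0]
    if (length(inner) == 0) inner <- idx
    rc <- arrayInd(idx, dim(image))
    tibble(label = as.integer(lab), area_px2 = area,
           clump_size = min(as.integer(ceiling(area / cfg$a_max)),
                            cfg$max_clump_size),
           x = mean(rc[, 2]) - 1, y = mean(rc[, 1]) - 1,
           pixels = list(idx), pixels_interior = list(inner))
  })
  out <- bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) empty else arrange(out, .data$label)
}

#' Measure segmented objects
#'
#' Computes, for each object, the mean and max pixel intensity over its
#' interior pixel set and the background-corrected mean
#' (`mean - background`, which may be <= 0; filtering happens downstream).
#'
#' @param image Numeric matrix of pixel intensities.
#' @param objects Tibble from [segment_objects()].
#' @param background Scalar background level (see [estimate_background()]).
#' @return The `objects` tibble with `mean`, `max` and `corrected_mean`
#'   columns added and the pixel list-columns dropped.
#' @export
measure_objects <- function(image, objects, background) {
  if (nrow(objects) > 0 &&
      any(lengths(objects$pixels_interior) == 0)) {
    abort("object with zero pixels cannot be measured")
  }
  stats <- purrr::map(objects$pixels_interior, function(idx) {
    v <- image[idx]
    c(mean = mean(v), max = max(v))
  })
  objects |>
    mutate(mean = purrr::map_dbl(stats, "mean"),
           max = purrr::map_dbl(stats, "max"),
           corrected_mean = .data$mean - background) |>
    select(-"pixels", -"pixels_interior") |>
    select("label", "area_px2", "mean", "max", "corrected_mean",
           "clump_size", "x", "y")
}

#' Quantify one fluorescence image
#'
#' Full per-image pipeline: estimate the background, segment objects by edge
#' detection, and measure each object's intensity. Deterministic for a fixed
#' input.
#'
#' @param image Numeric matrix of pixel intensities.
#' @param cfg A [segmentation_config()].
#' @param image_id Identifier copied into every output row.
#' @return A tibble with columns `image_id`, `label`, `area_px2`, `mean`,
#'   `max`, `corrected_mean`, `clump_size`, `x`, `y`; the estimated background
#'   level is attached as attribute `"background"`.
#' @export
quantify_image <- function(image, cfg = segmentation_config(),
                           image_id = "image") {
  bg <- estimate_background(image)
  objects <- segment_objects(image, cfg)
  measured <- measure_objects(image, objects, as.numeric(bg))
  out <- mutate(measured, image_id = image_id, .before = 1)
  attr(out, "background") <- as.numeric(bg)
  out
}

#' Read a grayscale image from TIFF or PNG
#'
#' Values are returned in native intensity units (`[0, 2^bit_depth - 1]`),
#' undoing the `[0, 1]` scaling the file formats use.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param bit_depth Bit depth used when the file was written (8 or 16).
#' @return Numeric matrix of pixel intensities.
#' @export
read_intensity_image <- function(path, bit_depth = 16) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(paste("unsupported image extension:", ext))
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * (2^bit_depth - 1)
}

#' Write a grayscale intensity image
#'
#' @param image Numeric matrix in intensity units.
#' @param path Output path (`.tif`/`.tiff` for 16-bit TIFF, `.png` for 8-bit
#'   PNG).
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_intensity_image <- function(image, path, bit_depth = 16) {
  scaled <- pmin(pmax(image / (2^bit_depth - 1), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(scaled, path, bits.per.sample = bit_depth),
    png = png::writePNG(scaled, path),
    abort(paste("unsupported image extension:", ext))
  )
  invisible(path)
}
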