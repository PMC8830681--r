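#' Specification of a synthetic microscopy scene
#'
#' Describes a single-channel fluorescence image to render: a flat background
#' with additive Gaussian pixel noise plus round cells drawn as filled discs of
#' uniform interior intensity. Clumps of 2-4 cells are rendered as chains of
#' tangent discs extending in +x from the listed center, so a clump's area is
#' approximately `clump_size` times the single-cell area.
#'
#' @param width,height Image size in pixels.
#' @param cells A data frame with one row per cell entry and columns
#'   `x`, `y` (center of the first disc, 0-based pixel coordinates),
#'   `radius` (px, > 0), `clump_size` (1-4) and `intensity` (true mean
#'   interior intensity).
#' @param background Background intensity level.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param bit_depth 8 or 16; intensities must fit in `[0, 2^bit_depth - 1]`.
#' @param seed Integer seed making the rendered image reproducible.
#'
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width, height, cells = NULL, background = 100,
                       noise_sd = 5, bit_depth = 16, seed = 1L) {
  if (!bit_depth %in% c(8L, 16L)) abort("`bit_depth` must be 8 or 16")
  maxval <- 2^bit_depth - 1
  if (is.null(cells)) {
    cells <- tibble(x = numeric(), y = numeric(), radius = numeric(),
                    clump_size = integer(), intensity = numeric())
  }
  cells <- as_tibble(cells)
  need <- c("x", "y", "radius", "clump_size", "intensity")
  if (!all(need %in% names(cells))) {
    abort(paste("`cells` must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(cells) > 0) {
    if (any(cells$radius <= 0)) abort("cell radii must be > 0")
    if (!all(cells$clump_size %in% 1:4)) abort("`clump_size` must be in 1..4")
    if (any(cells$intensity < 0 | cells$intensity > maxval)) {
      abort("cell intensities must lie within the bit-depth range")
    }
    # chain of tangent discs extends (clump_size - 1) * 2r in +x
    x_max <- cells$x + (cells$clump_size - 1) * 2 * cells$radius + cells$radius
    inside <- cells$x - cells$radius >= 0 & x_max <= width - 1 &
      cells$y - cells$radius >= 0 & cells$y + cells$radius <= height - 1
    if (!all(inside)) abort("all cells must lie fully inside the frame")
  }
  if (background < 0 || background > maxval) {
    abort("`background` must lie within the bit-depth range")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         cells = cells, background = background, noise_sd = noise_sd,
         bit_depth = as.integer(bit_depth), seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# Pixel mask (logical height x width matrix) of one cell entry: the union of
# clump_size tangent discs. Pixel centers are at 0-based integer coordinates;
# a pixel belongs to a disc when its center lies within radius of the disc
# center (<= r^2).
cell_entry_mask <- function(width, height, x, y, radius, clump_size) {
  px <- matrix(rep(0:(width - 1), each = height), nrow = height)
  py <- matrix(rep(0:(height - 1), times = width), nrow = height)
  mask <- matrix(FALSE, height, width)
  for (k in seq_len(clump_size) - 1) {
    cx <- x + 2 * radius * k
    mask <- mask | ((px - cx)^2 + (py - y)^2 <= radius^2)
  }
  mask
}

#' Render a synthetic scene
#'
#' Rasterizes a [scene_spec()]: pixels inside a cell take that cell's true
#' mean intensity, all others the background level, and independent Gaussian
#' noise of sd `noise_sd` is added everywhere. The result is clamped to the
#' bit-depth range. Identical spec (including seed) gives a bit-identical
#' image.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `rendered_scene` with elements `image` (numeric
#'   `height x width` matrix in intensity units), `truth` (tibble with one row
#'   per cell entry: `label`, `x`, `y`, `radius`, `clump_size`, `area_px`,
#'   `true_mean`) and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height; w <- spec$width
  img <- matrix(spec$background, h, w)
  owner <- matrix(0L, h, w)
  cells <- spec$cells
  truth <- tibble(label = integer(), x = numeric(), y = numeric(),
                  radius = numeric(), clump_size = integer(),
                  area_px = integer(), true_mean = numeric())
  for (i in seq_len(nrow(cells))) {
    m <- cell_entry_mask(w, h, cells$x[i], cells$y[i],
                         cells$radius[i], cells$clump_size[i])
    if (any(owner[m] != 0L)) {
      abort("cells from different list entries overlap: scene is ambiguous")
    }
    owner[m] <- i
    img[m] <- cells$intensity[i]
    truth <- bind_rows(truth, tibble(
      label = i, x = cells$x[i], y = cells$y[i], radius = cells$radius[i],
      clump_size = as.integer(cells$clump_size[i]),
      area_px = sum(m), true_mean = cells$intensity[i]
    ))
  }
  img <- withr::with_seed(spec$seed,
                          img + rnorm(length(img), 0, spec$noise_sd))
  img <- pmin(pmax(img, 0), 2^spec$bit_depth - 1)
  structure(list(image = img, truth = truth, spec = spec),
            class = "rendered_scene")
}

#' Place non-overlapping cells on a jittered grid
#'
#' Lays out `n` cell entries so that footprints (including clump chains) keep
#' at least `min_gap` pixels between entries, by assigning entries to grid
#' slots sized for the largest footprint and jittering within each slot.
#'
#' @param n Number of cell entries.
#' @param width,height Frame size in pixels.
#' @param radius Disc radius (px).
#' @param clump_sizes Integer vector recycled over entries (values 1-4).
#' @param min_gap Minimum gap between entry footprints (px).
#' @param seed Integer seed for the jitter.
#' @return A tibble with columns `x`, `y`, `radius`, `clump_size` (no
#'   intensities; add them before building a [scene_spec()]).
#' @export
place_cells <- function(n, width, height, radius = 10, clump_sizes = 1L,
                        min_gap = 6, seed = 1L) {
  clump <- rep_len(as.integer(clump_sizes), n)
  max_clump <- max(clump)
  slot_w <- (2 * max_clump - 1) * 2 * radius + min_gap + 2
  slot_h <- 2 * radius + min_gap + 2
  ncol_s <- floor((width - 2) / slot_w)
  nrow_s <- floor((height - 2) / slot_h)
  if (ncol_s * nrow_s < n) {
    abort(sprintf("frame too small: %d slots available for %d cells",
                  ncol_s * nrow_s, n))
  }
  withr::with_seed(seed, {
    slots <- sample.int(ncol_s * nrow_s, n)
    sx <- (slots - 1) %% ncol_s
    sy <- (slots - 1) %/% ncol_s
    jmax <- min_gap / 2
    tibble(
      x = 1 + sx * slot_w + radius + stats::runif(n, 0, jmax),
      y = 1 + sy * slot_h + radius + stats::runif(n, 0, jmax),
      radius = radius,
      clump_size = clump
    )
  })
}

#' Simulate a full phagocytosis imaging experiment
#'
#' For each timepoint of the design and each replicate, renders a scene whose
#' cells' true mean intensity is the oscillator value at that timepoint,
#' `max(0, rhythm_value(t))`, perturbed per cell by mean-preserving lognormal
#' dispersion (multiplicative biological spread). Ground truth is retained for
#' every cell.
#'
#' @param design An [experiment_design()].
#' @param truth A [ground_truth_rhythm()] driving the uptake intensity.
#' @param width,height Scene size in pixels.
#' @param radius Cell radius (px).
#' @param background,noise_sd,bit_depth Scene rendering parameters, see
#'   [scene_spec()].
#' @param dispersion_sdlog Lognormal sd (log scale) of per-cell intensity
#'   dispersion around the timepoint mean.
#' @param clump_sizes Clump sizes recycled over cells in each scene.
#' @return A list of class `phagocytosis_simulation` with `scenes` (tibble:
#'   `time_ps`, `replicate`, `scene` list-column of [render_scene()] results),
#'   `cell_truth` (tibble of all cells with their true intensities),
#'   `timepoint_truth` (tibble: `time_ps`, `expected_intensity`), the `design`
#'   and `truth`, and `n_clamped` (timepoint means truncated at 0).
#' @export
simulate_phagocytosis_experiment <- function(design, truth,
                                             width = 512, height = 512,
                                             radius = 10,
                                             background = 100, noise_sd = 5,
                                             bit_depth = 16,
                                             dispersion_sdlog = 0.1,
                                             clump_sizes = 1L) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "ground_truth_rhythm"))
  tp <- design_timepoints(design)
  mu <- rhythm_value(truth, tp, t0 = design$start)
  n_clamped <- sum(mu < 0)
  mu <- pmax(mu, 0)
  maxval <- 2^bit_depth - 1

  grid <- tidyr::expand_grid(t_idx = seq_along(tp),
                             replicate = seq_len(design$replicates))
  scenes <- purrr::pmap(grid, function(t_idx, replicate) {
    scene_seed <- design$seed + 1009L * t_idx + replicate
    n <- design$cells_per_image
    pos <- place_cells(n, width, height, radius = radius,
                       clump_sizes = clump_sizes, seed = scene_seed)
    intensities <- withr::with_seed(scene_seed + 1L, {
      sdl <- dispersion_sdlog
      mu[t_idx] * rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    })
    pos$intensity <- pmin(background + intensities, maxval)
    render_scene(scene_spec(width, height, cells = pos,
                            background = background, noise_sd = noise_sd,
                            bit_depth = bit_depth, seed = scene_seed + 2L))
  })

  scene_tbl <- tibble(time_ps = tp[grid$t_idx], replicate = grid$replicate,
                      scene = scenes)
  cell_truth <- purrr::pmap(
    list(scene_tbl$time_ps, scene_tbl$replicate, scene_tbl$scene),
    function(t, r, sc) mutate(sc$truth, time_ps = t, replicate = r,
                              .before = 1)
  ) |> bind_rows()

  structure(
    list(scenes = scene_tbl, cell_truth = cell_truth,
         timepoint_truth = tibble(time_ps = tp, expected_intensity = mu),
         design = design, truth = truth, n_clamped = n_clamped),
    class = "phagocytosis_simulation"
  )
}
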