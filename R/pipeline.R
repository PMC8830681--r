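default_config <- function() {
  list(
    workflow = NULL,
    seed = 1L,
    output_dir = "results",
    input = list(images = NULL, disaccharides = NULL, standard_curve = NULL),
    segmentation = list(a_min = 150, a_max = 460, max_clump_size = 4,
                        edge_threshold = 0.2),
    preprocessing = list(alpha = 0.05, g_min = 0.5, iqr_multiplier = 1.5,
                         background_signal = 0),
    criteria = list(period_min = 18, period_max = 30, ac_max = 0.15,
                    alpha = 0.05),
    time_bases = list(index_offset = 16, ct_offset = 12),
    design = list(start = 16, interval = 4, span = 24, replicates = 3,
                  cells_per_image = 20),
    rhythm = list(amplitude = 300, ac_coef = 0, period = 24, phase = pi,
                  equilibrium = 600, trend_slope = 0, noise_sd = 0),
    smooth = TRUE,
    detrend = TRUE,
    collapse_replicates = TRUE,
    comparisons = list()
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills in documented defaults, and validates
#' keys and value ranges. Unknown keys, missing required keys, and
#' out-of-range values are reported together in one itemized error.
#'
#' @param path Path to a YAML file. Must define at least `workflow`
#'   (`"simulate"`, `"phagocytosis"` or `"proteoglycan"`).
#' @return A validated `pipeline_config` list with all defaults materialized.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  problems <- character()

  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    problems <- c(problems,
                  paste("unknown key(s):", paste(unknown, collapse = ", ")))
  }
  for (k in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[k]]) && is.list(user[[k]]) &&
        !is.null(names(cfg[[k]]))) {
      bad <- setdiff(names(user[[k]]), names(cfg[[k]]))
      if (length(bad)) {
        problems <- c(problems, paste0("unknown key(s) under `", k, "`: ",
                                       paste(bad, collapse = ", ")))
      }
      cfg[[k]][names(user[[k]])] <- user[[k]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  if (is.null(cfg$workflow) ||
      !cfg$workflow %in% c("simulate", "phagocytosis", "proteoglycan")) {
    problems <- c(problems,
                  "`workflow` must be simulate, phagocytosis or proteoglycan")
  }
  cr <- cfg$criteria
  if (cr$period_min >= cr$period_max) {
    problems <- c(problems,
                  "`criteria.period_min` must be < `criteria.period_max`")
  }
  if (cr$ac_max < 0) problems <- c(problems, "`criteria.ac_max` must be >= 0")
  if (cr$alpha <= 0 || cr$alpha >= 1) {
    problems <- c(problems, "`criteria.alpha` must be in (0, 1)")
  }
  sg <- cfg$segmentation
  if (sg$a_min <= 0 || sg$a_min >= sg$a_max) {
    problems <- c(problems,
                  "`segmentation.a_min` must satisfy 0 < a_min < a_max")
  }
  if (cfg$design$interval <= 0) {
    problems <- c(problems, "`design.interval` must be > 0")
  }
  if (identical(cfg$workflow, "phagocytosis") &&
      is.null(cfg$input$images)) {
    problems <- c(problems, "`input.images` is required for phagocytosis")
  }
  if (identical(cfg$workflow, "proteoglycan") &&
      (is.null(cfg$input$disaccharides) || is.null(cfg$input$standard_curve))) {
    problems <- c(problems, paste("`input.disaccharides` and",
                                  "`input.standard_curve` are required",
                                  "for proteoglycan"))
  }
  if (length(problems)) {
    abort(paste0("invalid configuration:\n",
                 paste0("  - ", problems, collapse = "\n")))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

config_criteria <- function(cfg) {
  rhythm_criteria(cfg$criteria$period_min, cfg$criteria$period_max,
                  cfg$criteria$ac_max, cfg$criteria$alpha)
}

config_design <- function(cfg) {
  experiment_design(cfg$design$start, cfg$design$interval, cfg$design$span,
                    cfg$design$replicates, cfg$design$cells_per_image,
                    seed = cfg$seed)
}

config_truth <- function(cfg) {
  r <- cfg$rhythm
  ground_truth_rhythm(r$amplitude, r$ac_coef, r$period, r$phase,
                      r$equilibrium, r$trend_slope, r$noise_sd)
}

write_manifest <- function(dir, cfg, stages) {
  manifest <- list(
    package = "circaphage",
    version = as.character(utils::packageVersion("circaphage")),
    workflow = cfg$workflow,
    seed = cfg$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Run a configured workflow
#'
#' Executes one of the three workflows and writes all stage outputs, a JSON
#' run manifest (package version, seed, per-stage row counts) and a text
#' report under `config$output_dir`. Re-running with an identical config
#' reproduces identical outputs for the deterministic stages. A stage failure
#' aborts with the failing stage named and leaves a `FAILED` marker in the
#' output directory.
#'
#' * `simulate`: renders the full imaging experiment (one TIFF per
#'   timepoint/replicate), the per-cell ground-truth table, a disaccharide
#'   table, a standard curve, and a sidecar `metadata.yaml` echoing all
#'   generator parameters.
#' * `phagocytosis`: quantifies every image, preprocesses intensities, runs
#'   the configured comparisons, fits the oscillator to the timepoint means.
#' * `proteoglycan`: fits the standard curve, normalizes to ng/cell (or
#'   ng/ml), computes class totals, Z-scores and per-species rhythm verdicts.
#'
#' @param config A `pipeline_config` from [load_config()].
#' @return A list of the stage results (invisibly), with the manifest
#'   attached as `$manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  res <- tryCatch(
    switch(config$workflow,
      simulate = { stage <- "simulate"; run_simulate(config) },
      phagocytosis = { stage <- "phagocytosis"; run_phagocytosis(config) },
      proteoglycan = { stage <- "proteoglycan"; run_proteoglycan(config) }
    ),
    error = function(e) {
      writeLines(paste("failed at stage:", stage, "--", conditionMessage(e)),
                 file.path(config$output_dir, "FAILED"))
      abort(paste0("pipeline failed at stage `", stage, "`: ",
                   conditionMessage(e)))
    }
  )
  res$manifest <- write_manifest(config$output_dir, config, res$stage_counts)
  status <- write_report(res, config,
                         file.path(config$output_dir, "report.txt"))
  res$status <- status
  invisible(res)
}

run_simulate <- function(cfg) {
  design <- config_design(cfg)
  truth <- config_truth(cfg)
  sim <- simulate_phagocytosis_experiment(
    design, truth,
    background = 100, noise_sd = 5,
    dispersion_sdlog = 0.1
  )
  img_dir <- file.path(cfg$output_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::pmap_chr(
    sim$scenes,
    function(time_ps, replicate, scene) {
      p <- file.path(img_dir, sprintf("t%02d_r%d.tif", as.integer(time_ps),
                                      as.integer(replicate)))
      write_intensity_image(scene$image, p, scene$spec$bit_depth)
      p
    }
  )
  write.csv(sim$cell_truth, file.path(cfg$output_dir, "cell_truth.csv"),
            row.names = FALSE)
  curve <- simulate_standard_curve(2, 100, seq(0, 2e5, length.out = 8),
                                   noise_sd = 50, seed = cfg$seed)
  write.csv(curve, file.path(cfg$output_dir, "standard_curve.csv"),
            row.names = FALSE)
  yaml::write_yaml(
    c(unclass(cfg)[c("workflow", "seed", "design", "rhythm")],
      list(n_images = length(paths))),
    file.path(cfg$output_dir, "metadata.yaml")
  )
  list(simulation = sim, image_paths = paths, standard_curve_table = curve,
       stage_counts = list(images = length(paths),
                           cells = nrow(sim$cell_truth)))
}

run_phagocytosis <- function(cfg) {
  files <- list.files(cfg$input$images, pattern = "\\.(tiff?|png)$",
                      full.names = TRUE)
  if (length(files) == 0) abort("no images found under `input.images`")
  meta <- regmatches(basename(files),
                     regexec("t([0-9]+)_r([0-9]+)", basename(files)))
  seg <- segmentation_config(cfg$segmentation$a_min, cfg$segmentation$a_max,
                             cfg$segmentation$max_clump_size,
                             cfg$segmentation$edge_threshold)
  cells <- purrr::map2(files, meta, function(f, m) {
    if (length(m) < 3) abort(paste("cannot parse timepoint/replicate from",
                                   basename(f)))
    quantify_image(read_intensity_image(f), seg, image_id = basename(f)) |>
      mutate(time_ps = as.numeric(m[2]), replicate = as.integer(m[3]))
  }) |> bind_rows()
  write.csv(cells, file.path(cfg$output_dir, "cell_measurements.csv"),
            row.names = FALSE)

  prep <- preprocess_intensities(cells,
                                 cfg$preprocessing$background_signal,
                                 cfg$preprocessing$iqr_multiplier)
  removed <- attr(prep, "removed")
  summaries <- timepoint_summary(prep)
  comparisons <- purrr::map(cfg$comparisons, function(cmp) {
    compare_groups(
      mutate(prep, grp = as.character(.data$time_ps)),
      group = "grp",
      groups = as.character(c(cmp$group_a, cmp$group_b)),
      alpha = cmp$alpha %||% cfg$preprocessing$alpha,
      g_min = cmp$g_min %||% cfg$preprocessing$g_min
    )
  }) |> bind_rows()
  fit <- fit_eho(
    prep |> select("time_ps", "replicate", value = "log10_intensity"),
    criteria = config_criteria(cfg),
    collapse_replicates = cfg$collapse_replicates,
    detrend = cfg$detrend, smooth = cfg$smooth,
    id = "Abeta42_phagocytosis"
  )
  write.csv(tidy_eho_row(fit), file.path(cfg$output_dir, "rhythm_fit.csv"),
            row.names = FALSE)
  if (nrow(comparisons)) {
    write.csv(comparisons, file.path(cfg$output_dir, "comparisons.csv"),
              row.names = FALSE)
  }
  list(cells = cells, preprocessed = prep, removed = removed,
       summaries = summaries, comparisons = comparisons, fit = fit,
       stage_counts = list(
         images = length(files), cells = nrow(cells),
         removed_below_threshold = sum(removed$below_threshold_removed),
         removed_iqr = sum(removed$iqr_removed),
         retained = nrow(prep)))
}

run_proteoglycan <- function(cfg) {
  disacc <- as_tibble(read.csv(cfg$input$disaccharides))
  curve_tbl <- as_tibble(read.csv(cfg$input$standard_curve))
  curve <- fit_standard_curve(curve_tbl)
  norm <- normalize_disaccharides(disacc, curve)
  totals <- class_totals(norm)
  zmat <- zscore_matrix(filter(norm, .data$compartment == "cell"))
  rhythms <- species_rhythms(filter(norm, .data$compartment == "cell"),
                             criteria = config_criteria(cfg),
                             detrend = cfg$detrend, smooth = cfg$smooth)
  write.csv(select(norm, -dplyr::any_of("truth")),
            file.path(cfg$output_dir, "normalized.csv"), row.names = FALSE)
  write.csv(totals, file.path(cfg$output_dir, "class_totals.csv"),
            row.names = FALSE)
  zwide <- tidyr::pivot_wider(select(zmat, -"flat"),
                              names_from = "time_ps", values_from = "z",
                              names_prefix = "PS")
  write.csv(zwide, file.path(cfg$output_dir, "zscores.csv"),
            row.names = FALSE)
  write.csv(select(rhythms, -"fit"),
            file.path(cfg$output_dir, "species_rhythms.csv"),
            row.names = FALSE)
  list(standard_curve = curve, normalized = norm, totals = totals,
       zscores = zmat, rhythms = rhythms,
       stage_counts = list(measurements = nrow(norm),
                           species_fitted = nrow(rhythms)))
}

#' Write a human-readable run report
#'
#' Summarizes a completed run: rhythm verdicts with reason codes and PS/CT
#' times side by side, the comparison table with p, Hedges' g and the joint
#' verdict, and removal counts per preprocessing stage. An empty result (no
#' cells detected, nothing fitted) is stated explicitly and signalled with a
#' nonzero status.
#'
#' @param results A result list from [run_pipeline()].
#' @param config The `pipeline_config` used.
#' @param path Output text file.
#' @return Integer status, invisibly: 0 for a populated report, 1 for an
#'   empty result.
#' @export
write_report <- function(results, config, path) {
  lines <- c(sprintf("workflow: %s   seed: %d", config$workflow, config$seed),
             "")
  status <- 0L
  fmt_fit <- function(tbl) {
    c("rhythm verdicts:",
      sprintf("  %-24s period %5.1f h  zenith PS%-5.1f CT%-5.1f  p=%.3g  %s%s",
              tbl$id, tbl$period, tbl$zenith_ps,
              time_convert(tbl$zenith_ps, "PS", "CT"),
              tbl$p, ifelse(tbl$circadian, "circadian", "non-circadian"),
              ifelse(nchar(tbl$reasons) > 0,
                     paste0(" [", tbl$reasons, "]"), "")))
  }
  if (!is.null(results$fit)) {
    if (results$stage_counts$cells == 0) {
      lines <- c(lines, "EMPTY RESULT: no cells detected")
      status <- 1L
    } else {
      lines <- c(lines, fmt_fit(tidy_eho_row(results$fit)))
    }
    lines <- c(lines, "",
               sprintf("cells measured: %d, below threshold: %d, IQR: %d",
                       results$stage_counts$cells,
                       results$stage_counts$removed_below_threshold,
                       results$stage_counts$removed_iqr))
    if (!is.null(results$comparisons) && nrow(results$comparisons)) {
      lines <- c(lines, "", "comparisons:",
                 sprintf("  PS%s vs PS%s: p=%.3g g=%.3f (%s) -> %s",
                         results$comparisons$group1,
                         results$comparisons$group2,
                         results$comparisons$p, results$comparisons$g,
                         results$comparisons$effect_class,
                         ifelse(results$comparisons$significant,
                                "significant", "not significant")),
                 sprintf("significant contrasts: %d of %d",
                         sum(results$comparisons$significant),
                         nrow(results$comparisons)))
    }
  }
  if (!is.null(results$rhythms)) {
    if (nrow(results$rhythms) == 0) {
      lines <- c(lines, "EMPTY RESULT: no species fitted")
      status <- 1L
    } else {
      lines <- c(lines, fmt_fit(results$rhythms))
    }
  }
  if (!is.null(results$simulation)) {
    lines <- c(lines,
               sprintf("simulated %d images, %d cells (clamped means: %d)",
                       results$stage_counts$images,
                       results$stage_counts$cells,
                       results$simulation$n_clamped))
  }
  writeLines(lines, path)
  invisible(status)
}
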