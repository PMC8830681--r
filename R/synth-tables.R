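#' Sulfation-code vocabulary
#'
#' The disaccharide sulfation codes recognised for each glycosaminoglycan
#' class: heparan sulfate (HS) codes describe sulfation at the amide (N) and
#' carbons 2/6, chondroitin sulfate (CS) codes at carbons 2/4/6; `0S` is
#' unsulfated and `TriS` trisulfated.
#'
#' @param class `"HS"` or `"CS"`; if omitted, both vocabularies are returned
#'   as a named list.
#' @return Character vector of valid codes (or a named list of two).
#' @export
sulfation_codes <- function(class = NULL) {
  vocab <- list(
    HS = c("0S", "2S", "NS", "6S", "2S6S", "NS2S", "NS6S", "TriS"),
    CS = c("0S", "2S", "4S", "6S", "2S6S", "2S4S", "4S6S", "TriS")
  )
  if (is.null(class)) return(vocab)
  if (!class %in% names(vocab)) abort("`class` must be \"HS\" or \"CS\"")
  vocab[[class]]
}

check_sulfation_code <- function(class, code) {
  ok <- vapply(seq_along(code),
               function(i) code[i] %in% sulfation_codes(class[i]),
               logical(1))
  if (!all(ok)) {
    bad <- paste0(class[!ok], ":", code[!ok])
    abort(paste("unknown sulfation code(s):",
                paste(unique(bad), collapse = ", ")))
  }
  invisible(TRUE)
}

#' Simulate a disaccharide concentration table
#'
#' Generates raw per-sample amounts (ng) for a set of disaccharide species,
#' each driven by its own oscillator, over the timepoints and replicates of a
#' design. Negative draws are truncated at 0 and the truncation count is
#' recorded in the `"n_clamped"` attribute.
#'
#' @param species A data frame with columns `class` (`"HS"`/`"CS"`), `code`
#'   (a valid sulfation code for that class) and a list-column `truth` of
#'   [ground_truth_rhythm()] objects, one per species.
#' @param design An [experiment_design()].
#' @param compartment `"cell"`, `"spent_media"` or `"ECM"`.
#' @param seed Seed; defaults to `design$seed`.
#' @return A tibble with columns `class`, `code`, `compartment`, `time_ps`,
#'   `replicate`, `raw_ng`.
#' @export
simulate_disaccharide_series <- function(species, design,
                                         compartment = "cell",
                                         seed = design$seed) {
  species <- as_tibble(species)
  stopifnot(all(c("class", "code", "truth") %in% names(species)))
  if (!compartment %in% c("cell", "spent_media", "ECM")) {
    abort("`compartment` must be one of \"cell\", \"spent_media\", \"ECM\"")
  }
  check_sulfation_code(species$class, species$code)
  out <- purrr::pmap(
    list(species$class, species$code, species$truth, seq_len(nrow(species))),
    function(cls, code, tr, i) {
      simulate_rhythm_series(tr, design, id = paste(cls, code, sep = ":"),
                             seed = seed + i, clamp_zero = TRUE) |>
        mutate(class = cls, code = code, compartment = compartment)
    }
  )
  n_clamped <- sum(vapply(out, function(x) attr(x, "n_clamped"), integer(1)))
  out <- bind_rows(out) |>
    select("class", "code", "compartment", "time_ps", "replicate",
           raw_ng = "value")
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Simulate a cell-count standard curve
#'
#' Emulates a DNA-stain fluorescence assay standard curve: for each known cell
#' count, fluorescence is `slope * count + intercept` plus Gaussian noise.
#'
#' @param slope Fluorescence per cell; must be nonzero.
#' @param intercept Fluorescence at zero cells.
#' @param counts Numeric vector of known cell counts.
#' @param noise_sd Gaussian noise sd on fluorescence.
#' @param seed Integer seed.
#' @return A tibble with columns `cell_count`, `fluorescence`.
#' @export
simulate_standard_curve <- function(slope, intercept, counts,
                                    noise_sd = 0, seed = 1L) {
  if (slope == 0) abort("`slope` must be nonzero")
  fl <- withr::with_seed(seed, {
    slope * counts + intercept + rnorm(length(counts), 0, noise_sd)
  })
  tibble(cell_count = counts, fluorescence = fl)
}
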