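#' Surface-area transform
#'
#' Converts an item's surface area (m^2) onto the 1--5 scale with a log
#' transform, so that small changes in area for small objects matter as
#' much as large changes for large objects:
#' `1 + 4 * (log(area) - log(sa_min)) / (log(sa_max) - log(sa_min))`,
#' clamped to `[1, 5]`. With `integer_binning` (the default) the result is
#' rounded half-up to the nearest integer, matching the 0.2 granularity of
#' the published exposure scores (five integer dimensions averaged).
#'
#' @param area Surface area in m^2, strictly positive (vectorised).
#' @param sa_min,sa_max Anchor areas mapping to scores 1 and 5.
#' @param integer_binning Round the clamped score half-up to an integer.
#' @return Scores in 1--5.
#' @examples
#' surface_area_score(0.05)                 # anchor -> 1
#' surface_area_score(10)                   # anchor -> 5
#' surface_area_score(sqrt(0.05 * 10))      # geometric midpoint -> 3
#' @export
surface_area_score <- function(area, sa_min = 0.05, sa_max = 10,
                               integer_binning = TRUE) {
  if (any(is.na(area)) || any(area <= 0)) {
    abort("surface area must be strictly positive", class = "ffs_validation_error")
  }
  stopifnot(sa_min > 0, sa_min < sa_max)
  s <- 1 + 4 * (log(area) - log(sa_min)) / (log(sa_max) - log(sa_min))
  s <- pmin(pmax(s, 1), 5)
  if (integer_binning) round_half_up(s) else s
}

#' CFR-exposure potential score
#'
#' The exposure model's five dimensions -- likelihood of use by a young
#' child, bare-skin contact, mouthing, cumulative use, and the
#' log-transformed surface area -- are combined by an equally weighted
#' arithmetic mean: there is no empirical basis for weighting one exposure
#' route more heavily than another, so the output is a relative potential
#' for exposure between product types, not an absolute dose.
#'
#' @param evals Consolidated exposure evaluation rows.
#' @param config An [ffs_config()].
#' @return Numeric vector of exposure scores in `[1, 5]`.
#' @examples
#' ev <- tibble::tibble(type_id = "x", variant = "high", evaluator = "consensus",
#'   child_use = 5, bare_skin = 5, mouthing = 4, cumulative_use = 4,
#'   surface_area_m2 = sqrt(0.05 * 10))  # surface dimension scores 3
#' exposure_score(ev)  # mean of 5,5,4,4,3 = 4.2
#' @export
exposure_score <- function(evals, config = ffs_config()) {
  dims <- exposure_dimension_scores(evals, config)
  (dims$child_use + dims$bare_skin + dims$mouthing + dims$cumulative_use +
     dims$surface_area_score) / 5
}

#' Per-item exposure dimension scores
#'
#' @inheritParams exposure_score
#' @return The input plus `surface_area_score`.
#' @export
exposure_dimension_scores <- function(evals, config = ffs_config()) {
  tibble::as_tibble(evals) |>
    mutate(surface_area_score = surface_area_score(
      .data$surface_area_m2, sa_min = config$sa_min, sa_max = config$sa_max,
      integer_binning = config$sa_integer_binning))
}

#' Score a consolidated exposure-evaluation table
#'
#' @inheritParams exposure_score
#' @return A tibble with the dimension columns plus `exposure_score`.
#' @export
score_exposure <- function(evals, config = ffs_config()) {
  dims <- exposure_dimension_scores(evals, config)
  dims$exposure_score <- (dims$child_use + dims$bare_skin + dims$mouthing +
                            dims$cumulative_use + dims$surface_area_score) / 5
  dims
}
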