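#' Model and pipeline configuration
#'
#' All tunable constants of the scoring, reconciliation, and sensitivity
#' machinery in one validated object. Defaults are the study conditions:
#' the 0.009 m^3 combustible-volume cap, saturation of the junction score
#' at four junctions, the 0.56 dendrogram cut, and the smokers-materials /
#' candles ignition lexicon.
#'
#' @param volume_cap Combustible volume (m^3) at which the spread score
#'   saturates at 5. Default 0.009 (the volume of a small cushion).
#' @param junction_cap Junction count at which the junction score saturates
#'   at 5. Default 4 (an open box).
#' @param likert_min,likert_max Bounds of the ordinal instrument. 1 and 5.
#' @param sa_min,sa_max Surface-area anchors (m^2) of the log transform
#'   mapping area onto the 1--5 scale. Defaults 0.05 and 10 span the
#'   catalogue from a small cushion face to a large sofa envelope.
#' @param sa_integer_binning If `TRUE` (default) the log-transformed
#'   surface-area score is rounded half-up to an integer, so exposure
#'   scores are multiples of 0.2.
#' @param quartile_method Percentile estimator for the lowest-quartile
#'   aggregation: `"linear"` (linear interpolation between order
#'   statistics, the spreadsheet default) or `"type-1"` ... `"type-9"`
#'   naming the classical estimators.
#' @param linkage_method Agglomerative linkage: one of `"single"`,
#'   `"complete"`, `"average"` (default), `"ward"`.
#' @param cut_height Dendrogram cut height defining clusters. Default 0.56.
#' @param sensitivity_cap Ceiling applied when imputing systematic contact
#'   error. Default 5.
#' @param ignition_lexicon Lower-cased keyword stems; a narrative mentioning
#'   any of them (matched at word starts, so "smokers" and "smoking" both
#'   hit) gates the junction score into the fire model.
#' @param ignition_rule How a gated-out junction score is handled:
#'   `"exclude"` (default; ornateness alone carries the ignition dimension),
#'   `"zero"` (a literal 0 junction score is averaged in), or `"pool"`
#'   (junction and ornateness enter the quartile pool as separate values
#'   when gated, ornateness alone otherwise).
#' @param quadrant_threshold_rule `"midrange"` (default), `"median"`, or
#'   `"explicit"` (then supply `quadrant_thresholds`).
#' @param quadrant_thresholds Length-2 numeric `c(x, y)` used when
#'   `quadrant_threshold_rule = "explicit"`.
#' @param jitter_amplitude Half-width of the uniform jitter added to
#'   sensitivity-plot coordinates (never to scores). Default 0.05.
#' @param consensus_rule `"median-round-half-up"` (default; per-field
#'   median with half-integer ties rounded toward higher risk) or `"mean"`.
#'
#' @return A validated list of class `ffs_config`.
#' @examples
#' cfg <- ffs_config()
#' cfg$volume_cap
#' ffs_config(linkage_method = "ward", cut_height = 0.7)
#' @export
ffs_config <- function(volume_cap = 0.009,
                       junction_cap = 4L,
                       likert_min = 1L,
                       likert_max = 5L,
                       sa_min = 0.05,
                       sa_max = 10,
                       sa_integer_binning = TRUE,
                       quartile_method = "linear",
                       linkage_method = "average",
                       cut_height = 0.56,
                       sensitivity_cap = 5L,
                       ignition_lexicon = c("cigarette", "smoker", "smoking",
                                            "candle", "lighter", "match", "pipe"),
                       ignition_rule = "exclude",
                       quadrant_threshold_rule = "midrange",
                       quadrant_thresholds = NULL,
                       jitter_amplitude = 0.05,
                       consensus_rule = "median-round-half-up") {
  cfg <- list(
    volume_cap = volume_cap, junction_cap = as.integer(junction_cap),
    likert_min = as.integer(likert_min), likert_max = as.integer(likert_max),
    sa_min = sa_min, sa_max = sa_max, sa_integer_binning = sa_integer_binning,
    quartile_method = quartile_method, linkage_method = linkage_method,
    cut_height = cut_height, sensitivity_cap = as.integer(sensitivity_cap),
    ignition_lexicon = ignition_lexicon, ignition_rule = ignition_rule,
    quadrant_threshold_rule = quadrant_threshold_rule,
    quadrant_thresholds = quadrant_thresholds,
    jitter_amplitude = jitter_amplitude, consensus_rule = consensus_rule
  )
  validate_ffs_config(cfg)
}

validate_ffs_config <- function(cfg) {
  known <- c("volume_cap", "junction_cap", "likert_min", "likert_max",
             "sa_min", "sa_max", "sa_integer_binning", "quartile_method",
             "linkage_method", "cut_height", "sensitivity_cap",
             "ignition_lexicon", "ignition_rule", "quadrant_threshold_rule",
             "quadrant_thresholds", "jitter_amplitude", "consensus_rule")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(extra, collapse = ", ")),
          class = "ffs_config_error")
  }
  stopifnot(
    cfg$volume_cap > 0,
    cfg$junction_cap >= 1,
    cfg$likert_min < cfg$likert_max,
    cfg$sa_min < cfg$sa_max, cfg$sa_min > 0,
    cfg$cut_height >= 0,
    cfg$sensitivity_cap >= cfg$likert_max,
    length(cfg$ignition_lexicon) > 0,
    cfg$jitter_amplitude >= 0
  )
  cfg$quartile_method <- match.arg(cfg$quartile_method,
                                   c("linear", paste0("type-", 1:9)))
  cfg$linkage_method <- match.arg(cfg$linkage_method,
                                  c("average", "single", "complete", "ward"))
  cfg$ignition_rule <- match.arg(cfg$ignition_rule, c("exclude", "zero", "pool"))
  cfg$quadrant_threshold_rule <- match.arg(cfg$quadrant_threshold_rule,
                                           c("midrange", "median", "explicit"))
  if (cfg$quadrant_threshold_rule == "explicit" &&
      (is.null(cfg$quadrant_thresholds) || length(cfg$quadrant_thresholds) != 2)) {
    abort("quadrant_threshold_rule = 'explicit' requires quadrant_thresholds = c(x, y)",
          class = "ffs_config_error")
  }
  cfg$consensus_rule <- match.arg(cfg$consensus_rule, c("median-round-half-up", "mean"))
  structure(cfg, class = "ffs_config")
}

# quantile() type for a configured quartile method
quartile_type <- function(method) {
  if (identical(method, "linear")) return(7L)
  as.integer(sub("^type-", "", method))
}

# hclust method name for a configured linkage
linkage_hclust_method <- function(linkage) {
  switch(linkage,
    average = "average", single = "single", complete = "complete",
    ward = "ward.D2",
    abort(paste0("unknown linkage method: ", linkage), class = "ffs_config_error")
  )
}
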