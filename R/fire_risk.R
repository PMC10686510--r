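#' Junction-count transform
#'
#' Maps the number of junctions (joins between horizontal and vertical
#' upholstered surfaces, where a dropped smouldering or flaming object can
#' lodge) onto the 1--5 scale: zero junctions score 1, one scores 2, two
#' score 3, three score 4, and four or more score 5. An item with four
#' junctions is effectively an open box -- an ignition source can only
#' roll into a junction -- so risk saturates there.
#'
#' @param junction_count Non-negative integer vector of junction counts.
#' @param cap Count at which the score saturates (default 4).
#' @return Integer scores in 1--5.
#' @examples
#' junction_score(c(0, 1, 3, 6))  # 1 2 4 5
#' @export
junction_score <- function(junction_count, cap = 4L) {
  if (any(is.na(junction_count)) ||
      any(junction_count < 0 | junction_count != floor(junction_count))) {
    abort("junction_count must be a non-negative integer",
          class = "ffs_validation_error")
  }
  as.integer(pmin(junction_count, cap) + 1L)
}

#' Ignition-source gate on the narrative justification
#'
#' Junctions only matter for ignition sources that can fall into them --
#' cigarettes, candles, lighters -- so the junction score enters the fire
#' model only when the evaluators' narrative justification for the contact
#' score refers to candles or smokers' materials. Matching is
#' case-insensitive against lexicon stems anchored at word starts, so
#' "smokers" and "smoking" both hit.
#'
#' @param narrative Character vector of free-text narratives ("" allowed).
#' @param lexicon Non-empty character vector of lower-cased keyword stems.
#' @return Logical vector: `TRUE` where the junction score is gated in.
#' @examples
#' ignition_gate("user may drop a lit cigarette into the seat")  # TRUE
#' ignition_gate("risk only from a nearby halogen heater")       # FALSE
#' @export
ignition_gate <- function(narrative,
                          lexicon = ffs_config()$ignition_lexicon) {
  if (length(lexicon) == 0) {
    abort("ignition lexicon must be non-empty", class = "ffs_validation_error")
  }
  narrative <- dplyr::coalesce(as.character(narrative), "")
  pattern <- paste0("\\b(", paste(tolower(lexicon), collapse = "|"), ")")
  stringr::str_detect(tolower(narrative), pattern)
}

#' Combustible-volume transform
#'
#' Fire-spread risk is assumed to increase linearly with the combustible
#' (upholstered) volume of an item up to a maximum score of 5 at 0.009
#' m^3 -- the volume of a small cushion, above which post-ignition flame
#' spread is effectively guaranteed. The transform is affine from score 1
#' at zero volume and saturates at the cap.
#'
#' @param volume Non-negative volume in m^3 (vectorised).
#' @param cap Saturation volume in m^3 (default 0.009).
#' @return Real scores in 1--5.
#' @examples
#' volume_score(c(0, 0.0045, 0.009, 1))  # 1 3 5 5
#' @export
volume_score <- function(volume, cap = 0.009) {
  if (any(is.na(volume)) || any(volume < 0)) {
    abort("combustible volume must be non-negative", class = "ffs_validation_error")
  }
  stopifnot(cap > 0)
  1 + 4 * pmin(volume, cap) / cap
}

#' Ignition-dimension score from junction and ornateness inputs
#'
#' Two data categories feed the ignition dimension: the transformed
#' junction score (gated by the narrative, see [ignition_gate()]) and the
#' ornateness score. When the gate is active the dimension is their
#' arithmetic mean; when inactive the default rule (`"exclude"`) lets
#' ornateness carry the dimension alone, and the `"zero"` rule instead
#' averages in a literal 0 junction score.
#'
#' @param jscore Transformed junction score (1--5), vectorised.
#' @param gate Logical: is the junction score gated in?
#' @param ornateness Ornateness score (1--5).
#' @param rule `"exclude"` (default) or `"zero"`.
#' @return Real ignition-dimension scores.
#' @examples
#' ignition_dimension_score(4, TRUE, 3)    # 3.5
#' ignition_dimension_score(4, FALSE, 3)   # 3
#' @export
ignition_dimension_score <- function(jscore, gate, ornateness,
                                     rule = c("exclude", "zero")) {
  rule <- match.arg(rule)
  out_gated <- (jscore + ornateness) / 2
  out_ungated <- if (rule == "exclude") ornateness else ornateness / 2
  ifelse(gate, out_gated, out_ungated)
}

#' Lowest quartile of a score vector
#'
#' The failure-chain aggregation: injury requires contact with an ignition
#' source, then ignition, then spread, then a user unable to react, so low
#' dimension scores dominate -- but using the single minimum was judged too
#' deterministic given the uncertainty of the inputs, so the 25th
#' percentile hedges on the low scores without letting one of them decide
#' the output alone.
#'
#' @param values Non-empty numeric vector.
#' @param method Percentile estimator; `"linear"` (default) is linear
#'   interpolation between order statistics, `"type-1"` ... `"type-9"`
#'   select the classical estimators.
#' @return The 25th percentile, within `[min(values), max(values)]`.
#' @examples
#' lower_quartile(c(2, 4, 4, 5))  # 3.5
#' lower_quartile(c(1, 5))        # 2
#' @export
lower_quartile <- function(values, method = "linear") {
  if (length(values) == 0 || any(is.na(values))) {
    abort("lower_quartile needs a non-empty vector without missing values",
          class = "ffs_validation_error")
  }
  unname(quantile(values, probs = 0.25, type = quartile_type(method)))
}

#' Per-item fire dimension scores
#'
#' Expands consolidated fire evaluations into the four model dimensions:
#' contact likelihood (raw Likert), ignition (junction/ornateness
#' composite, narrative-gated), spread (volume transform), and reactive
#' capacity (raw Likert).
#'
#' @param evals Consolidated fire evaluation rows (see
#'   [consolidate_panel()]); one row per item variant.
#' @param config An [ffs_config()].
#' @return The input plus `contact_score`, `ignition_score`,
#'   `spread_score`, `reactivity_score`, `junction_gate_active`, and the
#'   intermediate `junction_transformed`.
#' @export
fire_dimension_scores <- function(evals, config = ffs_config()) {
  evals <- tibble::as_tibble(evals)
  gate <- ignition_gate(evals$ignition_narrative, config$ignition_lexicon)
  jsc <- junction_score(evals$junction_count, cap = config$junction_cap)
  rule <- if (config$ignition_rule == "zero") "zero" else "exclude"
  evals |>
    mutate(
      contact_score = as.numeric(.data$contact),
      junction_transformed = as.numeric(jsc),
      junction_gate_active = gate,
      ignition_score = ignition_dimension_score(jsc, gate, .data$ornateness,
                                                rule = rule),
      spread_score = volume_score(.data$combustible_volume_m3,
                                  cap = config$volume_cap),
      reactivity_score = as.numeric(.data$reactive_capacity)
    )
}

# per-row aggregation pools for the two model termini; under the "pool"
# rule junction and ornateness enter the quartile as separate values
fire_pools <- function(dims, config, include_reactivity) {
  purrr::pmap(
    list(dims$contact_score, dims$ignition_score, dims$spread_score,
         dims$reactivity_score, dims$junction_transformed,
         dims$junction_gate_active, as.numeric(dims$ornateness)),
    function(contact, ign, spread, react, jsc, gate, orn) {
      pool <- if (config$ignition_rule == "pool") {
        if (gate) c(contact, jsc, orn, spread) else c(contact, orn, spread)
      } else {
        c(contact, ign, spread)
      }
      if (include_reactivity) pool <- c(pool, react)
      pool
    }
  )
}

#' Injury- and damage-risk scores
#'
#' `injury_risk_score()` aggregates all four fire dimensions -- contact,
#' ignition, spread, reactive capacity -- by their lowest quartile.
#' `damage_risk_score()` is the secondary terminus of the model: property
#' damage does not depend on whether a person can react, so it aggregates
#' the three non-reactivity dimensions.
#'
#' @param evals Consolidated fire evaluation rows.
#' @param config An [ffs_config()].
#' @return Numeric vector of scores, one per row of `evals`.
#' @examples
#' ev <- tibble::tibble(type_id = "x", variant = "high", evaluator = "consensus",
#'   contact = 3, junction_count = 3, ornateness = 2, reactive_capacity = 2,
#'   combustible_volume_m3 = 0.009 / 8, ignition_narrative = "halogen heater only")
#' injury_risk_score(ev)  # 1.875
#' @export
injury_risk_score <- function(evals, config = ffs_config()) {
  dims <- fire_dimension_scores(evals, config)
  purrr::map_dbl(fire_pools(dims, config, include_reactivity = TRUE),
                 lower_quartile, method = config$quartile_method)
}

#' @rdname injury_risk_score
#' @export
damage_risk_score <- function(evals, config = ffs_config()) {
  dims <- fire_dimension_scores(evals, config)
  purrr::map_dbl(fire_pools(dims, config, include_reactivity = FALSE),
                 lower_quartile, method = config$quartile_method)
}

#' Score a consolidated fire-evaluation table
#'
#' Convenience wrapper computing dimension scores plus both model outputs.
#'
#' @inheritParams injury_risk_score
#' @return A tibble: the dimension columns of [fire_dimension_scores()]
#'   plus `injury_risk` and `damage_risk`.
#' @export
score_fire <- function(evals, config = ffs_config()) {
  dims <- fire_dimension_scores(evals, config)
  dims$injury_risk <- purrr::map_dbl(
    fire_pools(dims, config, include_reactivity = TRUE),
    lower_quartile, method = config$quartile_method)
  dims$damage_risk <- purrr::map_dbl(
    fire_pools(dims, config, include_reactivity = FALSE),
    lower_quartile, method = config$quartile_method)
  dims
}
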