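# shared builders and independent oracles

make_fire_eval <- function(type_id = "x", variant = "high",
                           evaluator = "consensus", contact = 3,
                           junction_count = 2, ornateness = 3,
                           reactive_capacity = 3,
                           combustible_volume_m3 = 0.004,
                           ignition_narrative = "dropped cigarette plausible") {
  tibble::tibble(type_id = type_id, variant = variant, evaluator = evaluator,
                 contact = contact, junction_count = junction_count,
                 ornateness = ornateness, reactive_capacity = reactive_capacity,
                 combustible_volume_m3 = combustible_volume_m3,
                 ignition_narrative = ignition_narrative)
}

make_exposure_eval <- function(type_id = "x", variant = "high",
                               evaluator = "consensus", child_use = 3,
                               bare_skin = 3, mouthing = 2, cumulative_use = 3,
                               surface_area_m2 = 0.5) {
  tibble::tibble(type_id = type_id, variant = variant, evaluator = evaluator,
                 child_use = child_use, bare_skin = bare_skin,
                 mouthing = mouthing, cumulative_use = cumulative_use,
                 surface_area_m2 = surface_area_m2)
}

random_fire_evals <- function(n, seed) {
  withr::with_seed(seed, make_fire_eval(
    type_id = sprintf("t%03d", seq_len(n)),
    variant = sample(c("low", "high"), n, replace = TRUE),
    contact = sample(1:5, n, replace = TRUE),
    junction_count = sample(0:8, n, replace = TRUE),
    ornateness = sample(1:5, n, replace = TRUE),
    reactive_capacity = sample(1:5, n, replace = TRUE),
    combustible_volume_m3 = runif(n, 0, 0.02),
    ignition_narrative = sample(c("a lit cigarette may fall in",
                                  "candle wax and flame nearby",
                                  "only radiant heat from a heater",
                                  ""), n, replace = TRUE)))
}

# independent lowest-quartile oracle: linear interpolation between order
# statistics at fractional index 0.25 * (n - 1), coded from the definition
oracle_q1 <- function(x) {
  s <- sort(x)
  h <- 0.25 * (length(s) - 1)
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  s[lo] + (h - floor(h)) * (s[hi] - s[lo])
}

# brute-force pairwise Euclidean norms
oracle_dist <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  }
  out
}
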