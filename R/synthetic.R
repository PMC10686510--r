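#' Archetype profiles for the synthetic catalogue generator
#'
#' Three latent archetypes emulate the contrasts the real catalogue shows:
#' `child-product` (high child use and mouthing, low contact with ignition
#' sources -- children do not smoke and are rarely left unsupervised near
#' smokers' materials), `resting-furniture` (large items people sleep and
#' smoke in: high contact, volume, and reactive-capacity scores), and
#' `small-accessory` (cushions, pads, covers). Each profile carries latent
#' means for every fire and exposure category, volume and surface-area
#' ranges, and the probability that an item's ignition narrative mentions
#' smokers' materials or candles.
#'
#' @return One row per archetype.
#' @export
archetype_profiles <- function() {
  tibble::tribble(
    ~archetype, ~contact, ~junctions, ~ornateness, ~reactive,
    ~volume_min, ~volume_max, ~child_use, ~bare_skin, ~mouthing,
    ~cumulative_use, ~area_min, ~area_max, ~lexicon_prob, ~small_child,
    "child-product",     1.5, 2, 2.5, 2.0, 0.001, 0.010, 4.5, 4.0, 4.0, 3.0, 0.10, 1.0, 0.2, TRUE,
    "resting-furniture", 4.0, 3, 3.0, 4.5, 0.050, 0.500, 1.5, 3.0, 1.0, 4.0, 2.00, 8.0, 0.9, FALSE,
    "small-accessory",   2.5, 0, 2.0, 2.0, 0.002, 0.009, 2.0, 3.5, 2.0, 2.5, 0.05, 0.5, 0.4, FALSE
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic furniture catalogue with known ground truth
#'
#' Draws `n_types` product types from an archetype mix, each with a
#' low-risk and a high-risk exemplar item (so `2 * n_types` item
#' variants). Latent high-variant values are at least the latent
#' low-variant values in every fire category by construction; the
#' inversions seen in real consolidated scores arise downstream from
#' evaluator noise, not from the latent truth. The truth table records
#' the latent values and the archetype (= true cluster label) before any
#' noise and is never consumed by the scoring pipeline.
#'
#' @param n_types Number of product types (>= 2).
#' @param archetype_mix Named probabilities over [archetype_profiles()]
#'   rows (default equal thirds).
#' @param seed Integer seed.
#' @return A list: `catalogue` (type table with `small_child_product`
#'   flags) and `truth` (one row per item variant with latent category
#'   values, the ignition-narrative mention flag, and `archetype`).
#' @examples
#' syn <- generate_catalogue(6, seed = 42)
#' nrow(syn$truth)  # 12 item variants
#' @export
generate_catalogue <- function(n_types = 30,
                               archetype_mix = NULL,
                               seed = 1L) {
  stopifnot(n_types >= 2)
  prof <- archetype_profiles()
  if (is.null(archetype_mix)) {
    archetype_mix <- setNames(rep(1 / nrow(prof), nrow(prof)), prof$archetype)
  }
  if (length(archetype_mix) == 0 || sum(archetype_mix) <= 0) {
    abort("archetype mix must be non-empty with positive weight",
          class = "ffs_validation_error")
  }
  unknown <- setdiff(names(archetype_mix), prof$archetype)
  if (length(unknown) > 0) {
    abort(paste0("unknown archetype(s): ", paste(unknown, collapse = ", ")),
          class = "ffs_validation_error")
  }
  withr::with_seed(seed, {
    arch <- sample(names(archetype_mix), n_types, replace = TRUE,
                   prob = archetype_mix / sum(archetype_mix))
    catalogue <- tibble::tibble(
      type_id = sprintf("type_%02d", seq_len(n_types)),
      display_name = sprintf("Synthetic %s %02d", arch, seq_len(n_types)),
      small_child_product = prof$small_child[match(arch, prof$archetype)],
      notes = "synthetic",
      archetype = arch
    )
    truth <- purrr::map(seq_len(n_types), function(i) {
      p <- prof[prof$archetype == arch[i], ]
      # per-type latent spread between the low and high exemplar
      off <- runif(4, 0.25, 1)
      low <- clamp(c(p$contact, p$junctions, p$ornateness, p$reactive) - off,
                   c(1, 0, 1, 1), 5)
      high <- clamp(c(p$contact, p$junctions, p$ornateness, p$reactive) + off,
                    c(1, 0, 1, 1), 5)
      vols <- sort(runif(2, p$volume_min, p$volume_max))
      areas <- sort(runif(2, p$area_min, p$area_max))
      expo <- c(p$child_use, p$bare_skin, p$mouthing, p$cumulative_use)
      eoff <- runif(4, 0, 0.5)
      mention <- runif(1) < p$lexicon_prob
      tibble::tibble(
        type_id = catalogue$type_id[i], archetype = arch[i],
        variant = c("low", "high"),
        contact = c(low[1], high[1]), junction_count = round(c(low[2], high[2])),
        ornateness = c(low[3], high[3]), reactive_capacity = c(low[4], high[4]),
        combustible_volume_m3 = vols,
        ignition_mention = mention,
        child_use = clamp(c(expo[1] - eoff[1], expo[1] + eoff[1]), 1, 5),
        bare_skin = clamp(c(expo[2] - eoff[2], expo[2] + eoff[2]), 1, 5),
        mouthing = clamp(c(expo[3] - eoff[3], expo[3] + eoff[3]), 1, 5),
        cumulative_use = clamp(c(expo[4] - eoff[4], expo[4] + eoff[4]), 1, 5),
        surface_area_m2 = areas
      )
    }) |> dplyr::bind_rows()
  })
  list(catalogue = catalogue, truth = truth)
}

narrative_with <- c(
  "user may drop a lit cigarette into the seat",
  "candle on a nearby shelf could fall onto the item",
  "smoking in this item while drowsy is plausible",
  "a lighter or match could be lost in the folds")
narrative_without <- c(
  "risk mainly from a nearby halogen heater",
  "electrical fault in adjacent appliances",
  "radiant heat from a fireplace at a distance",
  "no obvious route for an ignition source")

#' Generate evaluator panels for a synthetic catalogue
#'
#' Emulates independent evaluators scoring every questionnaire: each
#' ordinal score is the latent value plus Gaussian noise, rounded half-up
#' and clamped to the 1--5 instrument; junction counts get the same
#' treatment floored at zero; volumes and areas get multiplicative
#' log-normal noise of the same magnitude. Narratives are template
#' sentences that contain an ignition-lexicon stem exactly when the item's
#' latent `ignition_mention` flag is set, so all evaluators of an item
#' gate consistently. With `noise_sd = 0` every evaluator reproduces the
#' rounded latent values exactly.
#'
#' @param synthetic A [generate_catalogue()] result.
#' @param n_evaluators Number of evaluators per questionnaire (>= 1).
#' @param noise_sd Standard deviation of the evaluator noise (>= 0).
#' @param seed Integer seed.
#' @return A list of `fire` and `exposure` evaluation tibbles, both valid
#'   under [validate_evaluations()].
#' @export
generate_evaluations <- function(synthetic, n_evaluators = 3, noise_sd = 0.5,
                                 seed = 1L) {
  stopifnot(n_evaluators >= 1, noise_sd >= 0)
  truth <- synthetic$truth
  n <- nrow(truth)
  withr::with_seed(seed, {
    evs <- purrr::map(seq_len(n_evaluators), function(e) {
      noise <- function() rnorm(n, 0, noise_sd)
      ord <- function(latent) clamp(round_half_up(latent + noise()), 1, 5)
      fire <- tibble::tibble(
        type_id = truth$type_id, variant = truth$variant,
        evaluator = sprintf("evaluator_%d", e),
        contact = ord(truth$contact),
        junction_count = pmax(round_half_up(truth$junction_count + noise()), 0),
        ornateness = ord(truth$ornateness),
        reactive_capacity = ord(truth$reactive_capacity),
        combustible_volume_m3 = truth$combustible_volume_m3 * exp(noise()),
        ignition_narrative = ifelse(
          truth$ignition_mention,
          sample(narrative_with, n, replace = TRUE),
          sample(narrative_without, n, replace = TRUE))
      )
      exposure <- tibble::tibble(
        type_id = truth$type_id, variant = truth$variant,
        evaluator = sprintf("evaluator_%d", e),
        child_use = ord(truth$child_use),
        bare_skin = ord(truth$bare_skin),
        mouthing = ord(truth$mouthing),
        cumulative_use = ord(truth$cumulative_use),
        surface_area_m2 = truth$surface_area_m2 * exp(noise())
      )
      list(fire = fire, exposure = exposure)
    })
  })
  list(fire = dplyr::bind_rows(purrr::map(evs, "fire")),
       exposure = dplyr::bind_rows(purrr::map(evs, "exposure")))
}

#' Plant separable clusters in (injury, damage, exposure) space
#'
#' Test harness for the clustering stage: draws `k` centroids inside
#' `[0, 5]^3` with pairwise distance at least `separation` (rejection
#' sampling; impossible geometries raise an error) and scatters
#' `n_per_cluster` type-level score triples around each with isotropic
#' Gaussian spread, clamped to the score cube.
#'
#' @param k Number of clusters (>= 2).
#' @param separation Minimum centroid separation (> 0).
#' @param within_spread Within-cluster standard deviation.
#' @param n_per_cluster Types per cluster.
#' @param seed Integer seed.
#' @return A summaries-shaped tibble with `type_id`, `injury_mean`,
#'   `damage_mean`, `exposure_mean`, and the `true_cluster` label.
#' @export
plant_clusters <- function(k, separation, within_spread = 0.1,
                           n_per_cluster = 5, seed = 1L) {
  if (k < 2) abort("k must be at least 2", class = "ffs_validation_error")
  stopifnot(separation > 0, within_spread >= 0, n_per_cluster >= 1)
  if (separation > sqrt(3) * 5) {
    abort("infeasible geometry: separation exceeds the score-cube diameter",
          class = "ffs_validation_error")
  }
  withr::with_seed(seed, {
    centroids <- matrix(runif(3, 0.5, 4.5), nrow = 1)
    tries <- 0
    while (nrow(centroids) < k) {
      cand <- runif(3, 0.5, 4.5)
      if (all(sqrt(colSums((t(centroids) - cand)^2)) >= separation)) {
        centroids <- rbind(centroids, cand)
      }
      tries <- tries + 1
      if (tries > 20000) {
        abort("infeasible geometry: could not place centroids at the requested separation",
              class = "ffs_validation_error")
      }
    }
    pts <- purrr::map(seq_len(k), function(g) {
      m <- matrix(rnorm(3 * n_per_cluster, sd = within_spread),
                  ncol = 3, byrow = TRUE)
      sweep(m, 2, centroids[g, ], "+")
    })
    m <- clamp(do.call(rbind, pts), 0, 5)
  })
  tibble::tibble(
    type_id = sprintf("planted_%02d", seq_len(k * n_per_cluster)),
    injury_mean = m[, 1], damage_mean = m[, 2], exposure_mean = m[, 3],
    true_cluster = rep(seq_len(k), each = n_per_cluster)
  )
}
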