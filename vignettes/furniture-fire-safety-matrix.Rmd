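---
title: "The furniture fire-safety matrix: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The furniture fire-safety matrix: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffsmatrix)
```

## The problem

Fire-safety regulation for upholstered furniture has historically pushed
manufacturers toward chemical flame retardants (CFRs), additives that reduce
ignitability but migrate out of products into dust, skin, and -- for young
children -- mouths. Whether a given product type should be required to resist
ignition therefore trades two relative quantities against each other: how much
fire risk the product actually presents in use, and how much CFR exposure
treating it would create. Neither quantity can be measured absolutely at the
granularity of a product type, but both can be scored *relatively* from
structured expert judgement. This package implements that scoring matrix as a
reproducible pipeline: two models over evaluator questionnaires, reconciled by
ranking, quadrant classification, and clustering, and stress-tested by
systematic-error imputation.

## The fire-risk model

Fire injury is treated as a failure chain: an ignition source must contact the
item, the item must ignite, fire must spread, and the user must be unable to
react. Four dimensions represent the links:

* **Contact** -- evaluator Likert score (1--5) for the likelihood that the item
  meets an ignition source.
* **Ignition** -- a composite of the junction count and the ornateness score.
  Junctions (joins between horizontal and vertical upholstered surfaces) are
  where dropped smouldering objects lodge; `junction_score()` maps counts
  {0, 1, 2, 3, >=4} to scores {1, 2, 3, 4, 5}, saturating because a
  four-junction item is effectively an open box. Because junctions are only
  relevant to ignition sources that can fall into them, the junction score
  enters the model only when the item's narrative justification mentions
  smokers' materials or candles (`ignition_gate()`, matching lexicon stems at
  word starts so "smokers" and "smoking" both hit).
* **Spread** -- `volume_score()` maps combustible volume affinely onto 1--5,
  saturating at 0.009 m^3 (a small cushion), above which spread is assumed
  effectively guaranteed.
* **Reactive capacity** -- Likert score for the user's ability to detect a fire
  and move away (reduced by sleep, intoxication, age, disability).

The injury score is the **lowest quartile** of the four dimension scores
(`lower_quartile()`): a pure minimum would make the weakest link fully
deterministic, which overstates the certainty of the inputs, while a mean would
ignore the chain structure; the 25th percentile hedges on the low scores
without letting a single one decide. Property damage needs no victim, so
`damage_risk_score()` aggregates the three non-reactivity dimensions.

### Choices the published description leaves open

* **Junction/ornateness combination.** How the two ignition inputs merge into
  one dimension is not stated in prose. The default takes their arithmetic mean
  when the gate is active and lets ornateness carry the dimension alone when it
  is not. Two alternatives are selectable through `ffs_config(ignition_rule=)`:
  `"zero"` reads "the junction score would be set to 0" literally and averages
  a zero in, and `"pool"` skips the composite and puts both inputs into the
  quartile pool as separate values. The printed per-type scores (multiples of
  0.125) are consistent with several of these readings, so none can be
  reverse-engineered as uniquely correct; all three are implemented and tested
  for the invariants they share (bounds, monotonicity, gate independence).
* **Quartile estimator.** Unstated; the default is linear interpolation
  between order statistics (the common spreadsheet and statistical default,
  `quantile()` type 7), with the other classical estimators selectable.
* **Volume intercept.** "Linear increase up to a maximum of 5" fixes the slope
  and cap but not the intercept; the floor is set to 1 so the spread dimension
  shares the 1--5 range of the Likert dimensions.

## The CFR-exposure model

Five dimensions: likelihood of use by a young child (small bodies mean high
relative dose), bare-skin contact (dermal migration), mouthing (oral
migration), cumulative use (duration of contact), and surface area (the size
of the CFR reservoir). Surface area is mapped onto 1--5 by a log transform
(`surface_area_score()`), so that small absolute differences between small
items matter as much as large differences between large items. The anchors
default to 0.05 m^2 (a small cushion face) -> 1 and 10 m^2 (a large sofa
envelope) -> 5; the original transform's parameters live in an unpublished
spreadsheet, so these anchors are this package's own calibration, chosen so a
realistic catalogue spans the scale, and are configurable. By default the
transformed value is rounded half-up to an integer (`sa_integer_binning`),
which makes every exposure score a multiple of 0.2 -- the granularity the
published score table shows throughout.

The exposure score is the equally weighted arithmetic mean of the five
dimension scores: with no empirical basis for weighting one route above
another, equal weights are the only defensible choice, and the output is
explicitly a relative potential, not a dose.

## Consolidation

Evaluators scored questionnaires independently and then reconciled scores in a
moderated consolidation session. A discussion has no arithmetic rule, so
`consolidate_evaluations()` provides a reproducible stand-in: the per-field
median, with half-integer medians rounded *up* -- conservative toward higher
risk; a plain mean is selectable. Junction counts consolidate to the rounded
median, volumes and areas to the plain median, and narratives concatenate.
Genuinely missing cells (the external panel left two reactive-capacity cells
blank) are excluded from their field's consolidation, never imputed as zero.

## Reconciliation

Each product type was evaluated through a relatively high-risk and a
relatively low-risk exemplar item; `summarise_types()` averages the pair and
keeps the range. Inversions -- the low exemplar outscoring the high one --
are real features of judgement data and are preserved, never reordered.

* `rank_types()` orders types by a mean score, breaking ties
  lexicographically by `type_id` for determinism.
* `quadrant_classify()` marks relative thresholds on the injury (x) and
  exposure (y) axes; the upper-left quadrant (low fire risk, high exposure)
  is the policy-relevant region. "Relative thresholds" is unquantified in the
  source, so the default rule is the midrange of each axis, with median and
  explicit thresholds selectable. On the boundary, x = threshold counts as
  right and y = threshold as upper.
* `distance_matrix()` + `build_dendrogram()` + `cut_clusters()` cluster types
  by Euclidean distance over (injury, damage, exposure) means. The linkage
  behind the published dendrogram is unstated; the default is average linkage,
  with single, complete, and Ward selectable. A cut at height 0.56 defines
  clusters as the connected components of merges strictly below the line;
  leaves joined by no sub-cut merge are outliers, not one-member clusters.

`validate_dendrogram()` packages the reproduction experiment honestly: the
published clustering used per-type damage means that were only released in a
supplementary spreadsheet, so the experiment clusters the *printed* injury and
exposure coordinates, tries all four linkages at the 0.56 cut, and reports
adjusted-Rand agreement with the published five-group reading
(`reference_clusters()`) -- a report, not an assertion of ground truth.

## Sensitivity analysis

The contact dimension rests most heavily on judgement that could differ
systematically between evaluator groups (fire professionals vs researchers).
`sensitivity_sweep()` imputes an underestimate of 1--4 points on every contact
score, capped at 5, and recomputes all injury scores. Jitter (uniform,
amplitude 0.05, seeded) is added to plotting coordinates only -- stored scores
are never jittered. The original study judged by eye whether the vertical
score distributions still showed clusters; `separation_statistic()` makes
that judgement reproducible as the best mean silhouette over contiguous
splits of the sorted scores. It is declared plumbing, reported alongside the
jittered plot (`plot_sensitivity()`) so a human can still make the visual
call. `compare_evaluators()` reproduces the external-panel comparison: signed
per-category differences (external minus team) with missing cells propagated.

## The synthetic-data generator

Real evaluations cannot ship with the package, so `generate_catalogue()` and
`generate_evaluations()` produce catalogues with known ground truth. Three
archetypes emulate the real contrasts: child products (high child-use and
mouthing, low contact -- children do not smoke), resting furniture (large
items people sleep and smoke in), and small accessories. Latent low/high
variant values are ordered by construction; evaluator noise is additive
Gaussian on the latent ordinal, rounded half-up and clamped to 1--5 -- the
simplest mechanism that produces the low/high inversions the real table
shows. Narratives are template sentences containing an ignition-lexicon stem
exactly when the item's latent mention flag (drawn with the archetype's
probability) is set, so evaluators of one item gate consistently.
`plant_clusters()` places separable centroids in the score cube for
clustering-recovery experiments.

What the generator does **not** emulate: correlated errors between
evaluators, item-specific (rather than archetype-level) narrative content,
heavy-tailed or adversarial raters, and any numerical calibration to the
published score table. Passing tests on synthetic data therefore demonstrate
the pipeline's correctness and robustness properties, not agreement with any
particular real panel.

## Numerical conventions and test scale

Half-integer rounding is always half-up (away from zero), matching
spreadsheet behaviour and erring toward higher risk. Degenerate inputs fail
loudly: empty record sets, mixed items in one consolidation, all-equal axes
under the midrange quadrant rule, and all-identical values in the separation
statistic are errors, not silent defaults. Ward linkage maps to `hclust`'s
`ward.D2` (Ward's criterion on Euclidean distances).

The test suite exercises the quartile estimator against an independent
interpolation oracle on 1000 random vectors, model monotonicity on 500+
randomized evaluations, and planted-cluster recovery over 20 seeded
replicates of 15 points each -- sizes chosen to probe the properties densely
while keeping the default test run fast on a laptop.

## Limitations

The scores are relative, not probabilistic: they rank product types, they do
not estimate fire frequencies or CFR doses. Material flammability, heat
release, CFR chemistry, end-of-life release, and behaviour during an actual
fire are all outside the models' scope. The clustering reproduction is bounded
by what was published: without the supplementary damage means and the linkage
choice, agreement with the published grouping can only be reported, not
enforced.
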