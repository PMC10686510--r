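#' Summarise item scores per product type
#'
#' Each product type was evaluated through two exemplar items, one judged
#' relatively low risk and one relatively high risk. The type-level score
#' is the mean of the pair and the range is their spread; evaluator noise
#' can and does produce inversions (low variant scoring above the high
#' variant), which are preserved.
#'
#' @param scores A score table with `type_id`, `variant` (`"low"`/`"high"`)
#'   and any of `injury_risk`, `damage_risk`, `exposure_score`.
#' @return One row per type: `<dim>_low`, `<dim>_high`, `<dim>_mean` for
#'   each available dimension, in first-appearance order of `type_id`.
#' @export
summarise_types <- function(scores) {
  scores <- tibble::as_tibble(scores)
  stopifnot(all(c("type_id", "variant") %in% names(scores)))
  dims <- intersect(c("injury_risk", "damage_risk", "exposure_score"), names(scores))
  if (length(dims) == 0) {
    abort("no score columns to summarise", class = "ffs_validation_error")
  }
  rename_map <- c(injury_risk = "injury", damage_risk = "damage",
                  exposure_score = "exposure")
  long <- scores |>
    select(dplyr::all_of(c("type_id", "variant", dims))) |>
    tidyr::pivot_longer(dplyr::all_of(dims), names_to = "dim", values_to = "value") |>
    mutate(dim = rename_map[.data$dim])
  wide <- long |>
    tidyr::pivot_wider(names_from = c("dim", "variant"), values_from = "value",
                       names_sep = "_")
  for (d in unname(rename_map[dims])) {
    wide[[paste0(d, "_mean")]] <-
      (wide[[paste0(d, "_low")]] + wide[[paste0(d, "_high")]]) / 2
  }
  ord <- unlist(lapply(unname(rename_map[dims]),
                       function(d) paste0(d, c("_low", "_high", "_mean"))))
  wide[c("type_id", ord)] |>
    dplyr::slice(match(unique(scores$type_id), wide$type_id))
}

#' Low/high pair summary
#'
#' @param low,high Scores of the low- and high-risk variant (vectorised).
#' @return A tibble with `mean`, `min`, `max`; inverted pairs keep their
#'   labels but min/max are taken over the pair.
#' @examples
#' type_summary(1.88, 2.00)  # car-seat injury pair: mean 1.94
#' @export
type_summary <- function(low, high) {
  stopifnot(is.finite(low), is.finite(high))
  tibble::tibble(mean = (low + high) / 2, min = pmin(low, high),
                 max = pmax(low, high))
}

#' Rank product types by a summary score
#'
#' Stable descending ordering; tied scores occupy consecutive positions
#' ordered lexicographically by `type_id` so the ranking is deterministic.
#'
#' @param summaries A [summarise_types()] table.
#' @param key Column to rank by, e.g. `"injury_mean"` or `"exposure_mean"`.
#' @return The summaries ordered by rank, with a `rank` column prepended.
#' @export
rank_types <- function(summaries, key = "exposure_mean") {
  summaries <- tibble::as_tibble(summaries)
  if (!key %in% names(summaries)) {
    abort(paste0("unknown ranking key: ", key), class = "ffs_validation_error")
  }
  out <- summaries |>
    arrange(dplyr::desc(.data[[key]]), .data$type_id) |>
    mutate(rank = dplyr::row_number(), .before = 1)
  out
}

#' Count subset members among the top-k ranked types
#'
#' Operationalises claims of the form "12 of the 14 small-child product
#' types are in the top 15 exposure scores".
#'
#' @param ranking A [rank_types()] result.
#' @param subset Character vector of `type_id`s.
#' @param k Number of top positions to inspect.
#' @return Integer count.
#' @export
top_k_membership <- function(ranking, subset, k) {
  stopifnot(k >= 0)
  if (k > nrow(ranking)) {
    abort("k exceeds the number of ranked types", class = "ffs_validation_error")
  }
  sum(head(ranking$type_id, k) %in% subset)
}

#' Euclidean distance matrix over type-level scores
#'
#' @param summaries A [summarise_types()] table.
#' @param cols Coordinate columns; defaults to the three model outputs
#'   `injury_mean`, `damage_mean`, `exposure_mean` (any subset present may
#'   be supplied explicitly).
#' @return A symmetric matrix with zero diagonal, dimnames = `type_id`.
#' @export
distance_matrix <- function(summaries,
                            cols = c("injury_mean", "damage_mean", "exposure_mean")) {
  summaries <- tibble::as_tibble(summaries)
  missing <- setdiff(cols, names(summaries))
  if (length(missing) > 0) {
    abort(paste0("missing coordinate column(s): ", paste(missing, collapse = ", ")),
          class = "ffs_validation_error")
  }
  if (nrow(summaries) < 2) {
    abort("need at least two points", class = "ffs_validation_error")
  }
  m <- as.matrix(summaries[cols])
  if (!all(is.finite(m))) {
    abort("non-finite coordinate in distance computation",
          class = "ffs_validation_error")
  }
  rownames(m) <- summaries$type_id
  as.matrix(dist(m, method = "euclidean"))
}

#' Agglomerative cluster tree over product types
#'
#' Builds the merge tree over the rows of a distance matrix under the
#' configured linkage (`"ward"` is Ward's criterion on Euclidean
#' distances, `hclust` method `"ward.D2"`).
#'
#' @param d A symmetric distance matrix (e.g. from [distance_matrix()]) or
#'   a `dist` object.
#' @param linkage `"average"` (default), `"single"`, `"complete"`, `"ward"`.
#' @return An `ffs_tree`: the underlying `hclust` plus the linkage label.
#' @export
build_dendrogram <- function(d, linkage = "average") {
  method <- linkage_hclust_method(linkage)
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  hc <- hclust(d, method = method)
  structure(list(hclust = hc, linkage = linkage,
                 labels = hc$labels %||% as.character(seq_len(attr(d, "Size")))),
            class = "ffs_tree")
}

#' @export
print.ffs_tree <- function(x, ...) {
  cat("Agglomerative cluster tree:", length(x$labels), "leaves,",
      x$linkage, "linkage\n")
  invisible(x)
}

#' Cut a cluster tree at a height
#'
#' Clusters are the connected components formed by merges strictly below
#' the cut height -- the links that a horizontal line at that height on
#' the dendrogram would pass above. Leaves joined by no sub-height merge
#' are outliers, not one-member clusters.
#'
#' @param tree An [build_dendrogram()] result.
#' @param height Cut height (>= 0).
#' @return An `ffs_clusters` tibble: `type_id`, `cluster` (integer id in
#'   order of first leaf appearance, `NA` for outliers), `is_outlier`.
#' @export
cut_clusters <- function(tree, height = 0.56) {
  stopifnot(inherits(tree, "ffs_tree"), height >= 0)
  hc <- tree$hclust
  n <- length(tree$labels)
  # union-find over leaves, applying only merges below the cut
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  comp_of_node <- integer(nrow(hc$merge))  # component representative per internal node
  for (i in seq_len(nrow(hc$merge))) {
    if (hc$height[i] >= height) { comp_of_node[i] <- NA_integer_; next }
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    ra <- if (a < 0) find(-a) else find(comp_of_node[a])
    rb <- if (b < 0) find(-b) else find(comp_of_node[b])
    parent[rb] <- ra
    comp_of_node[i] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sizes <- table(roots)
  is_outlier <- sizes[as.character(roots)] == 1
  cluster <- rep(NA_integer_, n)
  nonsingle <- unique(roots[!is_outlier])
  for (k in seq_along(nonsingle)) cluster[roots == nonsingle[k]] <- k
  structure(
    tibble::tibble(type_id = tree$labels, cluster = cluster,
                   is_outlier = as.vector(is_outlier)),
    class = c("ffs_clusters", "tbl_df", "tbl", "data.frame"),
    cut_height = height, linkage = tree$linkage
  )
}

#' Quadrant classification on the injury--exposure plane
#'
#' Marks relative thresholds on the injury (x) and exposure (y) axes and
#' labels each type by its quadrant; the upper-left quadrant -- low fire
#' risk combined with high exposure potential -- is the policy-relevant
#' region. Boundary convention: a point exactly on the x threshold counts
#' as right, exactly on the y threshold counts as upper.
#'
#' @param summaries A [summarise_types()] table.
#' @param rule `"midrange"` (midpoint of observed min/max per axis,
#'   default), `"median"`, or `"explicit"`.
#' @param thresholds `c(x, y)` when `rule = "explicit"`.
#' @param x,y Coordinate columns (defaults `injury_mean`, `exposure_mean`).
#' @return The summaries plus a `quadrant` factor column; thresholds are
#'   attached as attribute `"thresholds"`.
#' @export
quadrant_classify <- function(summaries, rule = c("midrange", "median", "explicit"),
                              thresholds = NULL,
                              x = "injury_mean", y = "exposure_mean") {
  rule <- match.arg(rule)
  summaries <- tibble::as_tibble(summaries)
  xs <- summaries[[x]]; ys <- summaries[[y]]
  thr <- switch(rule,
    midrange = {
      if (diff(range(xs)) == 0 || diff(range(ys)) == 0) {
        abort("degenerate axis range: midrange thresholds undefined",
              class = "ffs_validation_error")
      }
      c(mean(range(xs)), mean(range(ys)))
    },
    median = c(median(xs), median(ys)),
    explicit = {
      if (is.null(thresholds) || length(thresholds) != 2) {
        abort("explicit rule needs thresholds = c(x, y)",
              class = "ffs_validation_error")
      }
      thresholds
    })
  right <- xs >= thr[1]; upper <- ys >= thr[2]
  lab <- dplyr::case_when(
    !right & upper ~ "upper-left",
    right & upper ~ "upper-right",
    !right & !upper ~ "lower-left",
    TRUE ~ "lower-right")
  out <- summaries |>
    mutate(quadrant = factor(lab, levels = c("upper-left", "upper-right",
                                             "lower-left", "lower-right")))
  attr(out, "thresholds") <- setNames(thr, c(x, y))
  out
}

#' Ellipse glyph parameters for the scatter plot
#'
#' Each type is drawn as an ellipse centred on its (injury mean, exposure
#' mean) with semi-axes equal to half the absolute low--high range on each
#' axis; a type whose variants agree collapses to a point.
#'
#' @param summaries A [summarise_types()] table (or the reference-score
#'   fixture).
#' @param x_prefix,y_prefix Dimension prefixes, default `"injury"` and
#'   `"exposure"`.
#' @return `type_id`, `center_x`, `center_y`, `semi_x`, `semi_y`.
#' @export
ellipse_params <- function(summaries, x_prefix = "injury", y_prefix = "exposure") {
  summaries <- tibble::as_tibble(summaries)
  g <- function(p, s) summaries[[paste0(p, s)]]
  tibble::tibble(
    type_id = summaries$type_id,
    center_x = g(x_prefix, "_mean"), center_y = g(y_prefix, "_mean"),
    semi_x = abs(g(x_prefix, "_high") - g(x_prefix, "_low")) / 2,
    semi_y = abs(g(y_prefix, "_high") - g(y_prefix, "_low")) / 2
  )
}

#' Export a cluster tree as Newick
#'
#' Leaf labels are `type_id`s; branch lengths are merge-height
#' differences, so root-to-leaf path lengths equal the root merge height.
#'
#' @param tree An `ffs_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(tree, path) {
  stopifnot(inherits(tree, "ffs_tree"))
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 is identical structure, 0 is chance-level agreement. Used to report
#' how closely a dendrogram cut reproduces a reference grouping and to
#' measure planted-cluster recovery.
#'
#' @param a,b Vectors of cluster labels (any type; `NA`s allowed and
#'   treated as one extra shared label).
#' @return A number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- addNA(factor(a), ifany = TRUE)
  b <- addNA(factor(b), ifany = TRUE)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxv <- (sum_a + sum_b) / 2
  if (maxv == expected) return(1)
  (sum_ij - expected) / (maxv - expected)
}

#' Reference cluster assignment from the published dendrogram reading
#'
#' The five multi-member product groupings plus three outliers read off
#' the published dendrogram at the 0.56 cut. Used as the comparison
#' partition for [validate_dendrogram()].
#'
#' @return `type_id`, `cluster` (1--5, `NA` for outliers), `is_outlier`.
#' @export
reference_clusters <- function() {
  groups <- list(
    `1` = c("playpens", "prams", "baby_mattress", "baby_changing_mat"),
    `2` = c("floor_cushion", "car_seat", "child_trailers_strollers",
            "separate_baby_upholstery", "bean_bag", "outdoor_furniture",
            "side_rails", "seat_pad", "outdoor_furniture_upholstery"),
    `3` = c("lightup_childrens_cushion", "baby_products_with_seat",
            "carry_cots", "baby_nests", "pillow", "bassinet", "play_mat"),
    `4` = c("padded_foot_stools", "footboard", "pet_beds"),
    `5` = c("headboard", "living_aids", "upholstered_bed_base", "armchairs")
  )
  outliers <- c("divan", "loose_stretch_covers", "scatter_cushion")
  tibble::tibble(
    type_id = c(unlist(groups, use.names = FALSE), outliers),
    cluster = c(rep(as.integer(names(groups)), lengths(groups)),
                rep(NA_integer_, length(outliers))),
    is_outlier = c(rep(FALSE, sum(lengths(groups))), rep(TRUE, length(outliers)))
  )
}

#' Dendrogram reproduction experiment
#'
#' The published dendrogram was cut at 0.56 over Euclidean distances in
#' (injury, damage, exposure) space, but the linkage was not reported and
#' the per-type damage means are only available in the study's
#' supplementary spreadsheet. This experiment clusters whatever coordinate
#' columns are available (by default the printed injury and exposure
#' means), tries every standard linkage at the cut, and reports agreement
#' with [reference_clusters()] as an adjusted Rand index -- a validation
#' report, not an assertion of ground truth.
#'
#' @param summaries Type-level scores; defaults to the packaged printed
#'   score table.
#' @param cols Coordinate columns to cluster over.
#' @param cut_height Cut height (default 0.56).
#' @param linkages Linkages to try.
#' @return One row per linkage: cluster/outlier counts, ARI against the
#'   reference partition, and the best row flagged.
#' @export
validate_dendrogram <- function(summaries = load_reference_scores(),
                                cols = c("injury_mean", "exposure_mean"),
                                cut_height = 0.56,
                                linkages = c("single", "complete", "average", "ward")) {
  ref <- reference_clusters()
  d <- distance_matrix(summaries, cols = cols)
  rows <- purrr::map(linkages, function(lk) {
    cl <- cut_clusters(build_dendrogram(d, linkage = lk), height = cut_height)
    j <- dplyr::left_join(cl, ref, by = "type_id", suffix = c("", "_ref"))
    tibble::tibble(
      linkage = lk,
      n_clusters = dplyr::n_distinct(cl$cluster, na.rm = TRUE),
      n_outliers = sum(cl$is_outlier),
      ari = adjusted_rand_index(j$cluster, j$cluster_ref)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$best <- out$ari == max(out$ari)
  out
}

#' @export
tidy.ffs_clusters <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("type_id", "cluster", "is_outlier")])
}

#' @export
glance.ffs_clusters <- function(x, ...) {
  tibble::tibble(
    n_types = nrow(x),
    n_clusters = dplyr::n_distinct(x$cluster, na.rm = TRUE),
    n_outliers = sum(x$is_outlier),
    cut_height = attr(x, "cut_height"),
    linkage = attr(x, "linkage")
  )
}

#' @export
tidy.ffs_tree <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(merge = seq_along(hc$height),
                 left = hc$merge[, 1], right = hc$merge[, 2],
                 height = hc$height)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
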