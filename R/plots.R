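#' Ranked bar chart of type scores with low/high ranges
#'
#' Bars are type means ordered by rank; whiskers span the low- and
#' high-variant scores (inversions show as whiskers crossing the bar top).
#'
#' @param summaries A [summarise_types()] table or the packaged reference
#'   scores.
#' @param key Dimension to rank by (`"injury_mean"`, `"exposure_mean"`,
#'   `"damage_mean"`).
#' @return A ggplot object.
#' @export
plot_ranking <- function(summaries, key = "injury_mean") {
  ranked <- rank_types(summaries, key = key)
  prefix <- sub("_mean$", "", key)
  lo <- paste0(prefix, "_low"); hi <- paste0(prefix, "_high")
  ranked$type_id <- factor(ranked$type_id, levels = rev(ranked$type_id))
  ggplot2::ggplot(ranked, ggplot2::aes(x = .data$type_id, y = .data[[key]])) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmin(.data[[lo]], .data[[hi]]),
      ymax = pmax(.data[[lo]], .data[[hi]])), width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste("mean", prefix, "score"),
                  title = paste("Furniture types ranked by", prefix, "score")) +
    ggplot2::theme_minimal()
}

#' Injury--exposure scatter with range ellipses and quadrant lines
#'
#' Each type sits at its (injury mean, exposure mean) with an ellipse
#' whose semi-axes are half the low--high range on each axis; dashed
#' lines mark the quadrant thresholds. Small-child products can be
#' highlighted by passing the catalogue.
#'
#' @param summaries A [summarise_types()] table.
#' @param rule,thresholds Passed to [quadrant_classify()].
#' @param catalogue Optional catalogue with `small_child_product` to
#'   colour points.
#' @param n_ellipse Vertices per ellipse outline.
#' @return A ggplot object.
#' @export
plot_quadrants <- function(summaries, rule = "midrange", thresholds = NULL,
                           catalogue = NULL, n_ellipse = 60) {
  q <- quadrant_classify(summaries, rule = rule, thresholds = thresholds)
  thr <- attr(q, "thresholds")
  ell <- ellipse_params(summaries)
  theta <- seq(0, 2 * pi, length.out = n_ellipse)
  outlines <- ell |>
    mutate(pts = purrr::pmap(list(.data$center_x, .data$center_y,
                                  .data$semi_x, .data$semi_y),
                             function(cx, cy, sx, sy)
                               tibble::tibble(ex = cx + sx * cos(theta),
                                              ey = cy + sy * sin(theta)))) |>
    select("type_id", "pts") |>
    tidyr::unnest("pts")
  if (!is.null(catalogue)) {
    q <- dplyr::left_join(q, catalogue[c("type_id", "small_child_product")],
                          by = "type_id")
  } else {
    q$small_child_product <- FALSE
  }
  ggplot2::ggplot(q, ggplot2::aes(x = .data$injury_mean, y = .data$exposure_mean)) +
    ggplot2::geom_path(data = outlines,
                       ggplot2::aes(x = .data$ex, y = .data$ey, group = .data$type_id),
                       colour = "grey75", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = thr[1], linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thr[2], linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$small_child_product)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue4",
                                            `TRUE` = "forestgreen"),
                                 name = "small-child product") +
    ggplot2::labs(x = "fire risk (injury) score", y = "CFR exposure score",
                  title = "Fire risk vs CFR exposure by furniture type") +
    ggplot2::theme_minimal()
}

#' Dendrogram with cut line
#'
#' @param tree An [build_dendrogram()] result.
#' @param cut_height Height of the horizontal cut line.
#' @return A ggplot object.
#' @export
plot_dendrogram <- function(tree, cut_height = 0.56) {
  stopifnot(inherits(tree, "ffs_tree"))
  hc <- tree$hclust
  n <- length(tree$labels)
  # leaf x-positions in plotting order, then segment coordinates per merge
  xpos <- numeric(n); xpos[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge)); node_y <- hc$height
  segs <- vector("list", nrow(hc$merge))
  pos <- function(id) if (id < 0) c(xpos[-id], 0) else c(node_x[id], node_y[id])
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1]); b <- pos(hc$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    segs[[i]] <- tibble::tibble(
      x = c(a[1], a[1], b[1]), xend = c(a[1], b[1], b[1]),
      y = c(a[2], hc$height[i], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], b[2]))
  }
  segs <- dplyr::bind_rows(segs)
  leaves <- tibble::tibble(x = seq_len(n), label = tree$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs, ggplot2::aes(
      x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)) +
    ggplot2::geom_hline(yintercept = cut_height, colour = "red",
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(x = NULL, y = "merge height",
                  title = paste0("Dendrogram (", tree$linkage,
                                 " linkage), cut at ", cut_height)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Jittered sensitivity plot
#'
#' Injury scores for every item variant against the imputed contact
#' error; jitter applies to plotting coordinates only, so vertical bands
#' of points at each error level can be judged for cluster structure.
#'
#' @param sweep An [sensitivity_sweep()] result.
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sweep) {
  ggplot2::ggplot(tidy(sweep), ggplot2::aes(x = .data$jitter_x,
                                            y = .data$jitter_y)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::scale_x_continuous(breaks = sort(unique(sweep$delta))) +
    ggplot2::labs(x = "imputed contact-score error (points)",
                  y = "fire risk (injury) score",
                  title = "Sensitivity of injury scores to systematic contact error") +
    ggplot2::theme_minimal()
}
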