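test_that("type summaries average the variant pair and keep inversions", {
  expect_equal(type_summary(1.88, 2.00)$mean, 1.94)
  ts <- type_summary(4.20, 3.20)
  expect_equal(ts$mean, 3.70)
  expect_equal(ts$min, 3.20)
  expect_equal(ts$max, 4.20)
  deg <- type_summary(2.5, 2.5)
  expect_equal(deg$mean, 2.5)
  expect_equal(deg$max - deg$min, 0)

  scores <- tibble::tibble(
    type_id = rep(c("a", "b"), each = 2), variant = rep(c("low", "high"), 2),
    injury_risk = c(2, 4, 3, 1), exposure_score = c(1, 2, 5, 4))
  sm <- summarise_types(scores)
  expect_equal(sm$injury_mean, c(3, 2))
  expect_equal(sm$exposure_mean, c(1.5, 4.5))
  expect_equal(sm$injury_low, c(2, 3))   # inversion in b preserved as labelled
})

test_that("ranking is a stable descending permutation with lexicographic ties", {
  ref <- load_reference_scores() |>
    dplyr::mutate(exposure_mean = (exposure_low + exposure_high) / 2)
  r <- rank_types(ref, "exposure_mean")
  expect_setequal(r$type_id, ref$type_id)
  expect_identical(r$type_id[1], "playpens")
  expect_true(all(diff(r$exposure_mean) <= 0))
  ties <- r |> dplyr::group_by(exposure_mean) |>
    dplyr::summarise(ok = all(type_id == sort(type_id)))
  expect_true(all(ties$ok))
  expect_error(rank_types(ref, "not_a_key"), class = "ffs_validation_error")

  withr::with_seed(8, {
    sm <- tibble::tibble(type_id = sprintf("t%02d", 1:20),
                         injury_mean = sample(seq(1, 5, 0.5), 20, TRUE))
    r2 <- rank_types(sm, "injury_mean")
    oracle <- sm[order(-sm$injury_mean, sm$type_id), ]
    expect_identical(r2$type_id, oracle$type_id)
  })
})

test_that("top-k membership counts match brute force", {
  ref <- load_reference_scores() |>
    dplyr::mutate(exposure_mean = (exposure_low + exposure_high) / 2)
  r <- rank_types(ref, "exposure_mean")
  kids <- load_catalogue()$type_id[load_catalogue()$small_child_product]
  expect_equal(top_k_membership(r, kids, 15), 12)
  expect_equal(top_k_membership(r, character(0), 15), 0)
  expect_equal(top_k_membership(r, kids, nrow(r)), length(kids))
  expect_error(top_k_membership(r, kids, 31), class = "ffs_validation_error")

  withr::with_seed(21, {
    sm <- tibble::tibble(type_id = letters[1:6], injury_mean = runif(6))
    r2 <- rank_types(sm, "injury_mean")
    subset <- sample(letters[1:6], 3)
    for (k in 0:6) {
      expect_equal(top_k_membership(r2, subset, k),
                   sum(r2$type_id[seq_len(k)] %in% subset))
    }
  })
})

test_that("distance matrix equals the brute-force pairwise-norm oracle", {
  expect_equal(distance_matrix(tibble::tibble(
    type_id = c("a", "b"), injury_mean = c(0, 3), damage_mean = c(0, 4),
    exposure_mean = c(0, 0)))["a", "b"], 5)

  withr::with_seed(3, {
    sm <- tibble::tibble(type_id = sprintf("p%d", 1:5),
                         injury_mean = runif(5, 0, 5),
                         damage_mean = runif(5, 0, 5),
                         exposure_mean = runif(5, 0, 5))
  })
  d <- distance_matrix(sm)
  expect_equal(unname(d), oracle_dist(as.matrix(sm[-1])), tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # triangle inequality
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
  expect_error(distance_matrix(sm[1, ]), class = "ffs_validation_error")
  sm$injury_mean[2] <- NA
  expect_error(distance_matrix(sm), class = "ffs_validation_error")
})

test_that("dendrograms merge as hand agglomeration predicts", {
  two <- tibble::tibble(type_id = c("a", "b"), injury_mean = c(0, 3),
                        damage_mean = c(0, 4), exposure_mean = 0)
  tr <- build_dendrogram(distance_matrix(two))
  expect_equal(length(tr$hclust$height), 1)
  expect_equal(tr$hclust$height, 5)

  line <- tibble::tibble(type_id = c("a", "b", "c"),
                         injury_mean = c(0, 1, 10), damage_mean = 0,
                         exposure_mean = 0)
  tr3 <- build_dendrogram(distance_matrix(line), linkage = "single")
  expect_equal(tr3$hclust$height[1], 1)
  expect_equal(length(tr3$hclust$height), 2)  # n - 1 merges
  expect_error(build_dendrogram(distance_matrix(line), linkage = "centroid"))
})

test_that("cluster cuts partition leaves with singletons as outliers", {
  withr::with_seed(14, {
    sm <- plant_clusters(2, separation = 3, within_spread = 0.1,
                         n_per_cluster = 4, seed = 140)
  })
  tr <- build_dendrogram(distance_matrix(sm))
  at0 <- cut_clusters(tr, 0)
  expect_true(all(at0$is_outlier))
  top <- cut_clusters(tr, max(tr$hclust$height) + 1)
  expect_equal(dplyr::n_distinct(top$cluster), 1)
  expect_false(any(top$is_outlier))
  mid <- cut_clusters(tr, 1.5)
  expect_equal(dplyr::n_distinct(mid$cluster, na.rm = TRUE), 2)
  expect_equal(adjusted_rand_index(mid$cluster, sm$true_cluster), 1)
  # every leaf appears exactly once at every height
  for (h in c(0, 0.2, 1, 3, 10)) {
    cl <- cut_clusters(tr, h)
    expect_setequal(cl$type_id, sm$type_id)
    expect_equal(nrow(cl), nrow(sm))
    expect_true(all(xor(is.na(cl$cluster), !cl$is_outlier)))
  }
  gl <- glance(cut_clusters(tr, 1.5))
  expect_equal(gl$n_clusters, 2)
  expect_equal(gl$cut_height, 1.5)
})

test_that("quadrant labels follow the boundary convention and sum to n", {
  sm <- tibble::tibble(type_id = c("a", "b", "c", "d"),
                       injury_mean = c(1, 4, 1, 4),
                       exposure_mean = c(4, 4, 1, 1))
  q <- quadrant_classify(sm)
  expect_equal(as.character(q$quadrant),
               c("upper-left", "upper-right", "lower-left", "lower-right"))
  # a point exactly on both thresholds is upper-right
  thr <- attr(q, "thresholds")
  onb <- quadrant_classify(dplyr::bind_rows(
    sm, tibble::tibble(type_id = "e", injury_mean = thr[1],
                       exposure_mean = thr[2])), rule = "explicit",
    thresholds = unname(thr))
  expect_equal(as.character(onb$quadrant[5]), "upper-right")

  withr::with_seed(9, {
    sm2 <- tibble::tibble(type_id = sprintf("t%02d", 1:40),
                          injury_mean = runif(40, 0, 5),
                          exposure_mean = runif(40, 0, 5))
    q2 <- quadrant_classify(sm2)
    t2 <- attr(q2, "thresholds")
    oracle <- ifelse(sm2$injury_mean >= t2[1],
                     ifelse(sm2$exposure_mean >= t2[2], "upper-right", "lower-right"),
                     ifelse(sm2$exposure_mean >= t2[2], "upper-left", "lower-left"))
    expect_equal(as.character(q2$quadrant), oracle)
    expect_equal(sum(table(q2$quadrant)), nrow(sm2))
  })
  flat <- tibble::tibble(type_id = c("a", "b"), injury_mean = 2,
                         exposure_mean = c(1, 2))
  expect_error(quadrant_classify(flat), class = "ffs_validation_error")
})

test_that("ellipse glyphs centre on means with half-range semi-axes", {
  ref <- load_reference_scores()
  e <- ellipse_params(ref)
  pillow <- e[e$type_id == "pillow", ]
  expect_equal(pillow$center_y, 3.70)
  expect_equal(pillow$semi_y, 0.50)
  flat <- ellipse_params(tibble::tibble(
    type_id = "z", injury_low = 2, injury_high = 2, injury_mean = 2,
    exposure_low = 3, exposure_high = 3, exposure_mean = 3))
  expect_equal(flat$semi_x, 0)
  expect_equal(flat$semi_y, 0)
  swapped <- ellipse_params(tibble::tibble(
    type_id = "s", injury_low = 4, injury_high = 2, injury_mean = 3,
    exposure_low = 1, exposure_high = 5, exposure_mean = 3))
  expect_equal(swapped$semi_x, 1)
  expect_equal(swapped$semi_y, 2)
})

test_that("newick export preserves leaves and root height", {
  sm <- plant_clusters(3, separation = 2, within_spread = 0.05,
                       n_per_cluster = 3, seed = 5)
  tr <- build_dendrogram(distance_matrix(sm))
  f <- withr::local_tempfile(fileext = ".nwk")
  export_newick(tr, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, sm$type_id)
  expect_equal(ape::Ntip(phy), nrow(sm))
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(17, {
    for (i in 1:20) {
      a <- sample(1:4, 30, TRUE)
      b <- sample(1:3, 30, TRUE)
      expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
})

test_that("the dendrogram reproduction experiment reports agreement per linkage", {
  rep <- validate_dendrogram()
  expect_setequal(rep$linkage, c("single", "complete", "average", "ward"))
  expect_true(all(rep$ari <= 1))
  expect_true(any(rep$best))
  expect_true(all(rep$n_clusters >= 1))
  # reference partition covers the catalogue exactly
  ref <- reference_clusters()
  expect_setequal(ref$type_id, load_reference_scores()$type_id)
  expect_equal(sum(ref$is_outlier), 3)
  expect_equal(dplyr::n_distinct(ref$cluster, na.rm = TRUE), 5)
})
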