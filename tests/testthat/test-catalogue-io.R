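test_that("evaluation CSVs round-trip through write and read", {
  fire <- random_fire_evals(12, seed = 11)
  fire$evaluator <- sprintf("e%02d", seq_len(nrow(fire)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_evaluations(fire, f, "fire")
  back <- read_evaluations(f, "fire")
  expect_equal(as.data.frame(back), as.data.frame(fire))

  expo <- make_exposure_eval(type_id = sprintf("t%d", 1:5),
                             evaluator = sprintf("e%d", 1:5),
                             surface_area_m2 = c(0.05, 0.3, 1, 4, 10))
  g <- withr::local_tempfile(fileext = ".csv")
  write_evaluations(expo, g, "exposure")
  expect_equal(as.data.frame(read_evaluations(g, "exposure")),
               as.data.frame(expo))
})

test_that("readers reject schema and validation problems precisely", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("type_id,variant,evaluator,contact", "a,low,e1,3"), f)
  expect_error(read_evaluations(f, "fire"), "junction_count",
               class = "ffs_schema_error")

  bad <- make_fire_eval(contact = 7)
  g <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, g)
  expect_error(read_evaluations(g, "fire"), "row 1",
               class = "ffs_validation_error")

  expect_error(validate_evaluations(make_fire_eval(combustible_volume_m3 = -1),
                                    "fire"),
               class = "ffs_validation_error")
  expect_error(validate_evaluations(make_exposure_eval(surface_area_m2 = 0),
                                    "exposure"),
               class = "ffs_validation_error")
  dup <- dplyr::bind_rows(make_fire_eval(), make_fire_eval())
  expect_error(validate_evaluations(dup, "fire"), "duplicate",
               class = "ffs_validation_error")
})

test_that("score tables write with fixed precision and read back to 1e-6", {
  withr::with_seed(5, {
    scores <- tibble::tibble(
      type_id = rep(sprintf("t%02d", 1:30), each = 2),
      variant = rep(c("low", "high"), 30),
      injury_risk = runif(60, 1, 5), damage_risk = runif(60, 1, 5),
      exposure_score = runif(60, 1, 5))
  })
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores(scores, f)
  expect_identical(readLines(f, n = 1),
                   "type_id,variant,injury_risk,damage_risk,exposure_score")
  back <- read_scores(f)
  expect_equal(back$injury_risk, scores$injury_risk, tolerance = 1e-6)
  expect_equal(back$exposure_score, scores$exposure_score, tolerance = 1e-6)

  g <- tempfile(fileext = ".csv")
  expect_error(write_scores(scores[0, ], g), class = "ffs_io_error")
  expect_false(file.exists(g))
})

test_that("consolidation follows the median-half-up rule and its edge cases", {
  recs <- make_fire_eval(evaluator = c("e1", "e2", "e3"),
                         contact = c(3, 4, 5), junction_count = c(2, 2, 3),
                         ornateness = c(2, 2, 2), reactive_capacity = c(1, 3, 3),
                         combustible_volume_m3 = c(0.002, 0.004, 0.01))
  cons <- consolidate_evaluations(recs, flavour = "fire")
  expect_identical(cons$evaluator, "consensus")
  expect_equal(cons$contact, 4)           # odd-n median
  expect_equal(cons$junction_count, 2)
  expect_equal(cons$combustible_volume_m3, 0.004)
  expect_match(cons$ignition_narrative, "cigarette")

  # half-integer median rounds up, toward higher risk
  two <- make_fire_eval(evaluator = c("e1", "e2"), contact = c(3, 4))
  expect_equal(consolidate_evaluations(two, flavour = "fire")$contact, 4)

  # identical evaluators reproduce their values
  same <- make_fire_eval(evaluator = c("e1", "e2", "e3"))
  cons2 <- consolidate_evaluations(same, flavour = "fire")
  expect_equal(cons2$contact, same$contact[1])
  expect_equal(cons2$combustible_volume_m3, same$combustible_volume_m3[1])

  expect_error(consolidate_evaluations(make_fire_eval()[0, ], flavour = "fire"),
               class = "ffs_validation_error")
  mixed <- make_fire_eval(type_id = c("a", "b"), evaluator = c("e1", "e1"))
  expect_error(consolidate_evaluations(mixed, flavour = "fire"),
               class = "ffs_validation_error")
})

test_that("consolidation is permutation-invariant and skips missing cells", {
  recs <- make_fire_eval(evaluator = c("e1", "e2", "e3", "e4"),
                         contact = c(2, 5, 3, 1), junction_count = c(0, 4, 1, 2),
                         ornateness = c(1, 2, 5, 4),
                         reactive_capacity = c(2, NA, 4, 3),
                         combustible_volume_m3 = c(0.001, 0.003, 0.009, 0.02))
  a <- consolidate_evaluations(recs, flavour = "fire")
  b <- consolidate_evaluations(recs[c(3, 1, 4, 2), ], flavour = "fire")
  expect_equal(as.data.frame(a), as.data.frame(b))
  # NA excluded: median of (2, 4, 3) = 3, never treated as 0
  expect_equal(a$reactive_capacity, 3)

  med_oracle <- function(x) { s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else ceiling((s[n / 2] + s[n / 2 + 1]) / 2) }
  withr::with_seed(7, {
    for (i in 1:25) {
      v <- sample(1:5, sample(2:7, 1), replace = TRUE)
      recs <- make_fire_eval(evaluator = sprintf("e%d", seq_along(v)), contact = v)
      expect_equal(consolidate_evaluations(recs, flavour = "fire")$contact,
                   med_oracle(v))
    }
  })
})

test_that("packaged fixtures load as printed, inversions intact", {
  fx <- load_fixtures()
  expect_equal(nrow(fx$catalogue), 30)
  expect_equal(sum(fx$catalogue$small_child_product), 14)

  ref <- fx$reference_scores
  expect_equal(nrow(ref), 30)
  num <- as.matrix(ref[-1])
  expect_true(all(num >= 1 & num <= 5))
  # low > high inversions are real and must be preserved
  pillow <- ref[ref$type_id == "pillow", ]
  expect_gt(pillow$exposure_low, pillow$exposure_high)

  car <- ref[ref$type_id == "car_seat", ]
  expect_equal(unlist(car[-1], use.names = FALSE),
               c(1.88, 2.00, 1.94, 3.40, 3.40, 3.40))

  panel <- fx$panel_evaluations
  expect_equal(panel$contact[panel$type_id == "armchairs" &
                               panel$variant == "high" &
                               panel$evaluator == "consensus"], 5)
  # genuinely missing reactive-capacity cells load as NA, not zero
  p3 <- panel[panel$type_id == "child_trailers_strollers" &
                panel$evaluator == "panel_3", ]
  expect_true(all(is.na(p3$reactive_capacity)))
})
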