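#' @name catalogue_io
#' @title Evaluation tables: schemas, readers, writers, packaged fixtures
#'
#' @description
#' Evaluations are tabular: one row per furniture item variant per
#' evaluator. Two flavours exist. Fire-risk rows carry the contact
#' likelihood, junction count, ornateness, reactive capacity, combustible
#' volume (m^3), and the free-text ignition narrative. Exposure rows carry
#' child use, bare-skin contact, mouthing, cumulative use, and surface
#' area (m^2). Ordinal fields are integers on the 1--5 instrument.
NULL

fire_columns <- c("type_id", "variant", "evaluator", "contact",
                  "junction_count", "ornateness", "reactive_capacity",
                  "combustible_volume_m3", "ignition_narrative")
exposure_columns <- c("type_id", "variant", "evaluator", "child_use",
                      "bare_skin", "mouthing", "cumulative_use",
                      "surface_area_m2")
score_columns <- c("type_id", "variant", "injury_risk", "damage_risk",
                   "exposure_score")

ordinal_fields <- function(flavour) {
  switch(flavour,
         fire = c("contact", "ornateness", "reactive_capacity"),
         exposure = c("child_use", "bare_skin", "mouthing", "cumulative_use"))
}

#' Read an evaluation table from CSV
#'
#' Reads and validates a comma-separated evaluation file (UTF-8, header
#' row mandatory, `.` decimal separator). Row order is preserved.
#'
#' @param path Path to the CSV file.
#' @param flavour `"fire"` or `"exposure"`.
#' @return A tibble of validated evaluation records.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "type_id,variant,evaluator,contact,junction_count,ornateness,reactive_capacity,combustible_volume_m3,ignition_narrative",
#'   "armchairs,high,e1,5,3,3,5,0.2,smokers materials likely"), f)
#' read_evaluations(f, "fire")
#' @export
read_evaluations <- function(path, flavour = c("fire", "exposure")) {
  flavour <- match.arg(flavour)
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "ffs_io_error")
  }
  want <- if (flavour == "fire") fire_columns else exposure_columns
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_guess()),
                        progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(want, names(df))
  if (length(missing) > 0) {
    abort(paste0("schema error: missing column(s) ", paste(missing, collapse = ", ")),
          class = "ffs_schema_error")
  }
  df <- df[want]
  if (flavour == "fire") {
    df$ignition_narrative <- dplyr::coalesce(as.character(df$ignition_narrative), "")
  }
  validate_evaluations(df, flavour)
}

#' Validate an in-memory evaluation table
#'
#' Enforces the record invariants: ordinal fields are integers within the
#' instrument bounds, junction counts are non-negative integers, volumes
#' are non-negative, surface areas strictly positive, and each
#' (item, evaluator) pair appears at most once.
#'
#' @param records A data frame of evaluation rows.
#' @inheritParams read_evaluations
#' @param config An [ffs_config()] supplying the instrument bounds.
#' @return The records as a tibble, invisibly validated.
#' @export
validate_evaluations <- function(records, flavour = c("fire", "exposure"),
                                 config = ffs_config()) {
  flavour <- match.arg(flavour)
  records <- tibble::as_tibble(records)
  bad_row <- function(field, idx) {
    abort(sprintf("validation error: %s out of range at row %d", field, idx[1]),
          class = "ffs_validation_error")
  }
  for (f in ordinal_fields(flavour)) {
    v <- records[[f]]
    bad <- which(!is.na(v) &
                   (v < config$likert_min | v > config$likert_max | v != floor(v)))
    if (length(bad) > 0) bad_row(f, bad)
  }
  if (flavour == "fire") {
    v <- records$junction_count
    bad <- which(!is.na(v) & (v < 0 | v != floor(v)))
    if (length(bad) > 0) bad_row("junction_count", bad)
    v <- records$combustible_volume_m3
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) bad_row("combustible_volume_m3", bad)
  } else {
    v <- records$surface_area_m2
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad) > 0) bad_row("surface_area_m2", bad)
  }
  key <- paste(records$type_id, records$variant, records$evaluator, sep = "\r")
  if (anyDuplicated(key) > 0) {
    abort(sprintf("duplicate (item, evaluator) record at row %d", anyDuplicated(key)),
          class = "ffs_validation_error")
  }
  records
}

#' Write an evaluation table to CSV
#'
#' @param records A validated evaluation tibble.
#' @param path Output path.
#' @inheritParams read_evaluations
#' @return `path`, invisibly.
#' @export
write_evaluations <- function(records, path, flavour = c("fire", "exposure")) {
  flavour <- match.arg(flavour)
  records <- validate_evaluations(records, flavour)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Write scored items to CSV
#'
#' Writes the `type_id,variant,injury_risk,damage_risk,exposure_score`
#' table with fixed 6-decimal formatting, so a read-back reproduces the
#' values to 1e-6.
#'
#' @param scores A non-empty data frame containing the score columns.
#'   Missing score columns are written as empty cells.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  if (is.null(scores) || nrow(scores) == 0) {
    abort("refusing to write an empty score table", class = "ffs_io_error")
  }
  out <- tibble::tibble(type_id = as.character(scores$type_id),
                        variant = as.character(scores$variant))
  for (col in c("injury_risk", "damage_risk", "exposure_score")) {
    v <- if (col %in% names(scores)) scores[[col]] else rep(NA_real_, nrow(scores))
    out[[col]] <- ifelse(is.na(v), "", sprintf("%.6f", v))
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a score table written by [write_scores()]
#'
#' @param path Path to a scores CSV.
#' @return A tibble with numeric score columns.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "ffs_io_error")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(score_columns, names(df))
  if (length(missing) > 0) {
    abort(paste0("schema error: missing column(s) ", paste(missing, collapse = ", ")),
          class = "ffs_schema_error")
  }
  df |> mutate(across(c("injury_risk", "damage_risk", "exposure_score"), as.numeric))
}

#' Consolidate several evaluators' records for one item into a consensus record
#'
#' The study's consensus was reached in a moderated consolidation session;
#' this is the reproducible arithmetic stand-in. Under the default rule
#' each numeric field is consolidated by its per-field median with
#' half-integer medians rounded up, i.e. toward higher risk; junction
#' counts are rounded to the nearest integer (half up) and volumes/areas
#' keep the plain median. Narratives are concatenated. Missing cells are
#' excluded from the field's consolidation, never imputed as zero.
#'
#' @param records Evaluation rows, all for the same `(type_id, variant)`.
#' @param rule `"median-round-half-up"` (default) or `"mean"`.
#' @inheritParams read_evaluations
#' @return A one-row tibble with `evaluator = "consensus"`.
#' @examples
#' recs <- tibble::tibble(
#'   type_id = "armchairs", variant = "high", evaluator = c("e1", "e2", "e3"),
#'   contact = c(3L, 4L, 5L), junction_count = c(3L, 3L, 4L),
#'   ornateness = c(2L, 3L, 3L), reactive_capacity = c(5L, 4L, 5L),
#'   combustible_volume_m3 = c(0.2, 0.25, 0.2),
#'   ignition_narrative = c("smoking in chair", "dropped cigarette", "candle nearby"))
#' consolidate_evaluations(recs, flavour = "fire")
#' @export
consolidate_evaluations <- function(records,
                                    rule = c("median-round-half-up", "mean"),
                                    flavour = c("fire", "exposure")) {
  rule <- match.arg(rule)
  flavour <- match.arg(flavour)
  if (is.null(records) || nrow(records) == 0) {
    abort("cannot consolidate an empty record set", class = "ffs_validation_error")
  }
  if (length(unique(paste(records$type_id, records$variant))) != 1) {
    abort("records mix more than one item; consolidate one (type, variant) at a time",
          class = "ffs_validation_error")
  }
  ord <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    if (rule == "mean") mean(x) else round_half_up(median(x))
  }
  med <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA_real_)
    median(x)
  }
  out <- tibble::tibble(type_id = records$type_id[1],
                        variant = records$variant[1],
                        evaluator = "consensus")
  if (flavour == "fire") {
    out$contact <- ord(records$contact)
    out$junction_count <- round_half_up(med(records$junction_count))
    out$ornateness <- ord(records$ornateness)
    out$reactive_capacity <- ord(records$reactive_capacity)
    out$combustible_volume_m3 <- med(records$combustible_volume_m3)
    narr <- records$ignition_narrative
    narr <- narr[!is.na(narr) & nzchar(narr)]
    out$ignition_narrative <- paste(narr, collapse = " | ")
  } else {
    out$child_use <- ord(records$child_use)
    out$bare_skin <- ord(records$bare_skin)
    out$mouthing <- ord(records$mouthing)
    out$cumulative_use <- ord(records$cumulative_use)
    out$surface_area_m2 <- med(records$surface_area_m2)
  }
  out
}

#' Consolidate a full multi-evaluator panel, item by item
#'
#' Applies [consolidate_evaluations()] within every `(type_id, variant)`
#' group of a raw evaluation table.
#'
#' @inheritParams consolidate_evaluations
#' @return One consensus row per item variant, in first-appearance order.
#' @export
consolidate_panel <- function(records,
                              rule = c("median-round-half-up", "mean"),
                              flavour = c("fire", "exposure")) {
  rule <- match.arg(rule)
  flavour <- match.arg(flavour)
  records |>
    mutate(.item = paste(.data$type_id, .data$variant, sep = "\r")) |>
    group_by(.item = factor(.data$.item, levels = unique(.data$.item))) |>
    group_modify(~ consolidate_evaluations(.x, rule = rule, flavour = flavour)) |>
    ungroup() |>
    select(-".item")
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "ffsmatrix")
  if (!nzchar(p)) abort(paste0("packaged fixture not found: ", file),
                        class = "ffs_io_error")
  p
}

fixture_md5 <- c(
  catalogue.csv        = "8188915bb257c7abe0ae5e3c43ea1da1",
  reference_scores.csv = "85877362553ccd58e12707a9ddf7d137",
  panel_comparison.csv = "9161f7eb1eccddfa805ab290972026c2"
)

check_fixture <- function(file) {
  p <- fixture_path(file)
  got <- unname(tools::md5sum(p))
  if (!identical(got, unname(fixture_md5[[file]]))) {
    abort(paste0("packaged fixture failed its integrity checksum: ", file),
          class = "ffs_integrity_error")
  }
  p
}

#' Packaged fixtures: catalogue, printed reference scores, panel comparison
#'
#' `load_catalogue()` returns the 30 furniture product types with the
#' small-child flag set for the 14 types intended for use by infants and
#' very young children. `load_reference_scores()` returns the printed
#' per-type low/high/mean injury-risk and CFR-exposure scores; the table
#' is loaded exactly as printed, including low > high inversions (e.g. the
#' pillow's exposure scores), which are meaningful and must not be
#' reordered. `load_panel_evaluations()` returns the external-validation
#' records: fire-model category scores for four product types from the
#' consolidated research team and three advisory-panel members (two
#' reactive-capacity cells are genuinely missing and load as `NA`; some
#' panel scores sit outside the 1--5 instrument and are preserved as
#' given). `load_fixtures()` bundles all three.
#'
#' Every loader verifies an MD5 checksum of the packaged file first.
#'
#' @return A tibble (`load_catalogue`, `load_reference_scores`,
#'   `load_panel_evaluations`) or a named list of the three
#'   (`load_fixtures`).
#' @examples
#' nrow(load_catalogue())        # 30 product types
#' sum(load_catalogue()$small_child_product)  # 14 small-child types
#' @export
load_catalogue <- function() {
  readr::read_csv(check_fixture("catalogue.csv"),
                  col_types = "cclc", progress = FALSE) |>
    mutate(notes = dplyr::coalesce(.data$notes, ""))
}

#' @rdname load_catalogue
#' @export
load_reference_scores <- function() {
  df <- readr::read_csv(check_fixture("reference_scores.csv"),
                        col_types = "cdddddd", progress = FALSE)
  stopifnot(nrow(df) == 30)
  df
}

#' @rdname load_catalogue
#' @export
load_panel_evaluations <- function() {
  readr::read_csv(check_fixture("panel_comparison.csv"),
                  col_types = "cccdddd", progress = FALSE)
}

#' @rdname load_catalogue
#' @export
load_fixtures <- function() {
  list(catalogue = load_catalogue(),
       reference_scores = load_reference_scores(),
       panel_evaluations = load_panel_evaluations())
}
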