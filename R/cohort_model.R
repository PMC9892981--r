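#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Fixed visit labels for the two-timepoint design.
VISIT_LEVELS <- c("pre", "post")
SEX_LEVELS <- c("male", "female")
SMOKING_LEVELS <- c("nonsmoker", "current_smoker")
DRINKING_LEVELS <- c("nondrinker", "current_drinker")
DIET_LEVELS <- c("good", "bad")

#' Column dictionary for cohort files
#'
#' The machine-readable schema of the per-visit cohort table: one row per
#' column, with its type, unit and whether it is mandatory. The same
#' dictionary ships as `inst/extdata/cohort_columns.csv`. All measurements
#' are fixed in the units used throughout (cm, kg, mmHg, mg/dL); there is no
#' unit auto-detection.
#'
#' @return A tibble with columns `column`, `type`, `unit`, `required`,
#'   `description`.
#' @export
cohort_schema <- function() {
  path <- system.file("extdata", "cohort_columns.csv", package = "msacoach")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Plausibility bounds for clinical indicators
#'
#' Default hard ranges used by [validate_cohort()]. Values outside these
#' bounds are validation errors unless `relaxed = TRUE`.
#'
#' @param ... named overrides, each a length-2 numeric `c(lower, upper)`.
#' @return Named list of `c(lower, upper)` bounds.
#' @export
cohort_bounds <- function(...) {
  bounds <- list(
    height = c(100, 220), weight = c(25, 300), wc = c(40, 200),
    sbp = c(70, 250), dbp = c(40, 150), fbs = c(40, 500),
    tg = c(20, 2000), hdl = c(10, 150)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(bounds))
    if (length(bad)) abort(paste0("unknown bound: ", bad[1]), class = "msacoach_schema_error")
    bounds[names(dots)] <- dots
  }
  bounds
}

.required_columns <- function() {
  c("id", "visit", "sex", "age", "med_lipid", "med_bp", "med_glucose",
    "height", "weight", "wc", "sbp", "dbp", "fbs", "tg", "hdl",
    "exercise_per_week", "smoking", "drinking", "drink_freq_per_week",
    "drink_amount_ml", "alcohol_content_pct", "sleep_hours", "stress",
    "diet", "steps_per_day")
}

.fail_rows <- function(ok, what) {
  bad <- which(!ok)
  abort(
    sprintf("%s violated at row(s) %s", what,
            paste(utils::head(bad, 5), collapse = ", ")),
    class = "msacoach_validation_error"
  )
}

#' Validate a cohort table
#'
#' Checks the per-visit cohort table against the domain invariants:
#' column presence and types, visit labels, positive measurements,
#' `sbp > dbp`, plausibility bounds, lifestyle ranges (stress 1-5, sleep in
#' (0, 24), non-negative drinking fields, nondrinkers with zero drinking
#' frequency), eligibility age >= 20, uniqueness of (id, visit), and
#' constancy of participant-level fields (sex, age, medication flags)
#' across a participant's visits.
#'
#' @param cohort data frame with the columns of [cohort_schema()].
#' @param bounds plausibility bounds, see [cohort_bounds()].
#' @param relaxed if `TRUE`, skip the plausibility-bound checks (invariants
#'   such as `sbp > dbp` are still enforced).
#' @return `cohort` (as a tibble), invisibly, if valid; otherwise an error
#'   of class `msacoach_schema_error`, `msacoach_duplicate_error` or
#'   `msacoach_validation_error`.
#' @export
validate_cohort <- function(cohort, bounds = cohort_bounds(), relaxed = FALSE) {
  cohort <- as_tibble(cohort)
  missing_cols <- setdiff(.required_columns(), names(cohort))
  if (length(missing_cols)) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "msacoach_schema_error")
  }
  if (!all(cohort$visit %in% VISIT_LEVELS)) {
    .fail_rows(cohort$visit %in% VISIT_LEVELS, "visit label in {pre, post}")
  }
  key <- paste(cohort$id, cohort$visit)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (id, visit) record: %s", key[duplicated(key)][1]),
          class = "msacoach_duplicate_error")
  }
  if (!all(cohort$sex %in% SEX_LEVELS)) .fail_rows(cohort$sex %in% SEX_LEVELS, "sex in {male, female}")
  if (!all(cohort$smoking %in% SMOKING_LEVELS)) .fail_rows(cohort$smoking %in% SMOKING_LEVELS, "smoking level")
  if (!all(cohort$drinking %in% DRINKING_LEVELS)) .fail_rows(cohort$drinking %in% DRINKING_LEVELS, "drinking level")
  if (!all(cohort$diet %in% DIET_LEVELS)) .fail_rows(cohort$diet %in% DIET_LEVELS, "diet in {good, bad}")

  num_cols <- c("height", "weight", "wc", "sbp", "dbp", "fbs", "tg", "hdl")
  for (v in num_cols) {
    x <- cohort[[v]]
    if (!is.numeric(x)) abort(paste0("column ", v, " must be numeric"), class = "msacoach_schema_error")
    if (any(!is.finite(x) | x <= 0)) .fail_rows(is.finite(x) & x > 0, paste(v, "strictly positive"))
  }
  if (any(cohort$sbp <= cohort$dbp)) .fail_rows(cohort$sbp > cohort$dbp, "sbp > dbp")
  if (!relaxed) {
    for (v in names(bounds)) {
      x <- cohort[[v]]
      ok <- x >= bounds[[v]][1] & x <= bounds[[v]][2]
      if (!all(ok)) .fail_rows(ok, sprintf("%s within [%g, %g]", v, bounds[[v]][1], bounds[[v]][2]))
    }
  }
  if (any(cohort$age < 20)) .fail_rows(cohort$age >= 20, "age >= 20 (eligibility)")
  ok <- cohort$stress %in% 1:5
  if (!all(ok)) .fail_rows(ok, "stress in {1..5}")
  ok <- cohort$sleep_hours > 0 & cohort$sleep_hours < 24
  if (!all(ok)) .fail_rows(ok, "sleep_hours in (0, 24)")
  for (v in c("exercise_per_week", "drink_freq_per_week", "drink_amount_ml",
              "alcohol_content_pct")) {
    ok <- is.finite(cohort[[v]]) & cohort[[v]] >= 0
    if (!all(ok)) .fail_rows(ok, paste(v, ">= 0"))
  }
  ok <- cohort$alcohol_content_pct <= 100
  if (!all(ok)) .fail_rows(ok, "alcohol_content_pct <= 100")
  ok <- !(cohort$drinking == "nondrinker" & cohort$drink_freq_per_week > 0)
  if (!all(ok)) .fail_rows(ok, "nondrinker implies drink_freq_per_week = 0")

  # participant-level fields must not vary across a participant's visits
  per <- dplyr::summarise(
    dplyr::group_by(cohort, .data$id),
    varying = dplyr::n_distinct(.data$sex) > 1 |
      dplyr::n_distinct(.data$age) > 1 |
      dplyr::n_distinct(.data$med_lipid) > 1 |
      dplyr::n_distinct(.data$med_bp) > 1 |
      dplyr::n_distinct(.data$med_glucose) > 1,
    .groups = "drop"
  )
  if (any(per$varying)) {
    abort(sprintf("participant-level fields differ across visits for id %s",
                  per$id[per$varying][1]),
          class = "msacoach_validation_error")
  }
  invisible(cohort)
}

.cohort_col_types <- function() {
  readr::cols(
    id = readr::col_character(), visit = readr::col_character(),
    sex = readr::col_character(), age = readr::col_double(),
    med_lipid = readr::col_logical(), med_bp = readr::col_logical(),
    med_glucose = readr::col_logical(),
    smoking = readr::col_character(), drinking = readr::col_character(),
    diet = readr::col_character(), stress = readr::col_integer(),
    .default = readr::col_double()
  )
}

#' Read a cohort from a delimited text file
#'
#' Reads a comma-delimited, UTF-8, headered cohort file (one row per
#' participant visit) and validates it. Missing medication flags are
#' filled as `FALSE`; a missing `steps_per_day` column is filled as `NA`
#' (step summaries may be attached later from a daily series).
#'
#' @param path file path.
#' @param bounds,relaxed passed to [validate_cohort()].
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path, bounds = cohort_bounds(), relaxed = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "msacoach_io_error")
  cohort <- readr::read_csv(path, col_types = .cohort_col_types(),
                            progress = FALSE)
  for (v in c("med_lipid", "med_bp", "med_glucose")) {
    if (!v %in% names(cohort)) cohort[[v]] <- FALSE
    cohort[[v]][is.na(cohort[[v]])] <- FALSE
  }
  if (!"steps_per_day" %in% names(cohort)) cohort$steps_per_day <- NA_real_
  validate_cohort(cohort, bounds = bounds, relaxed = relaxed)
  cohort[, .required_columns()]
}

#' Write a cohort to a delimited text file
#'
#' Deterministic column order (the dictionary order of [cohort_schema()])
#' and row order (id, then visit pre before post), so identical cohorts
#' produce byte-identical files. `read_cohort(write_cohort(x))` is the
#' identity on values.
#'
#' @param cohort validated cohort tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (NROW(cohort) == 0) abort("refusing to write an empty cohort", class = "msacoach_validation_error")
  cohort <- as_tibble(cohort)[, .required_columns()]
  cohort <- cohort[order(cohort$id, match(cohort$visit, VISIT_LEVELS)), ]
  ok <- tryCatch({ readr::write_csv(cohort, path, progress = FALSE); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("cannot write ", path, ": ", conditionMessage(ok)),
                         class = "msacoach_io_error")
  invisible(path)
}

#' Aligned pre/post pairs for one variable
#'
#' Complete-case extraction: participants with both visits and a
#' non-missing value at each contribute one (before, after) pair, aligned
#' by id. Mirrors the trial's complete-case analysis set.
#'
#' @param cohort cohort tibble (per-visit rows).
#' @param var column name of the variable.
#' @return list with `id`, `before`, `after` (equal-length vectors).
#' @export
paired_values <- function(cohort, var) {
  pre <- cohort[cohort$visit == "pre", c("id", var)]
  post <- cohort[cohort$visit == "post", c("id", var)]
  m <- merge(pre, post, by = "id", suffixes = c("_pre", "_post"))
  b <- m[[paste0(var, "_pre")]]
  a <- m[[paste0(var, "_post")]]
  keep <- !is.na(b) & !is.na(a)
  list(id = m$id[keep], before = b[keep], after = a[keep])
}
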