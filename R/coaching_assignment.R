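MANAGEMENT_GROUPS <- c("obesity", "blood_pressure", "blood_sugar", "lipid", "normal")

# indicator -> management group owning it, and the criterion that gates it
.INDICATOR_GROUP <- c(wc = "obesity", sbp = "blood_pressure",
                      dbp = "blood_pressure", fbs = "blood_sugar",
                      tg = "lipid", hdl = "lipid")
.INDICATOR_CRITERION <- c(wc = "obesity", sbp = "hypertension",
                          dbp = "hypertension", fbs = "hyperglycemia",
                          tg = "high_tg", hdl = "low_hdl")

#' Ten-year age bands of the reference table
#'
#' @param age ages in years (>= 20).
#' @return character band labels `20-29`, ..., `60-69`, `70+`.
#' @export
age_band <- function(age) {
  if (any(age < 20)) abort("reference table covers ages >= 20", class = "msacoach_reference_error")
  ifelse(age >= 70, "70+",
         paste0(floor(age / 10) * 10, "-", floor(age / 10) * 10 + 9))
}

#' Sex/age reference strata for indicator standardization
#'
#' Loads a reference table of per-stratum means and SDs for the six
#' coaching-relevant indicators (WC, SBP, DBP, FBS, TG, HDL-C). The
#' bundled default is a synthetic table with plausible Korean-adult
#' strata (it stands in for population checkup statistics, which are not
#' distributed with the package); supply your own CSV with columns
#' `sex`, `age_band`, `indicator`, `mean`, `sd` for real use.
#'
#' @param path CSV path; default the bundled synthetic table.
#' @return tibble reference table; SDs are checked to be positive.
#' @export
read_reference_table <- function(path = system.file(
    "extdata", "reference_strata_synthetic.csv", package = "msacoach")) {
  ref <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sex", "age_band", "indicator", "mean", "sd")
  if (!all(need %in% names(ref))) {
    abort("reference table needs columns sex, age_band, indicator, mean, sd",
          class = "msacoach_schema_error")
  }
  if (any(ref$sd <= 0)) abort("reference SDs must be positive", class = "msacoach_reference_error")
  ref
}

.ref_lookup <- function(ref, sex, band, indicator) {
  row <- ref[ref$sex == sex & ref$age_band == band & ref$indicator == indicator, ]
  if (nrow(row) != 1) {
    abort(sprintf("no reference stratum for (%s, %s, %s)", sex, band, indicator),
          class = "msacoach_reference_error")
  }
  row
}

#' Severity z-score against the sex/age reference
#'
#' `(value - stratum mean) / stratum SD`, sign-flipped for HDL-C so that
#' larger always means worse (HDL is the only protective indicator among
#' the five criteria). Severity is invariant to affine re-expression of
#' the measurement units.
#'
#' @param value measured value.
#' @param indicator one of `wc`, `sbp`, `dbp`, `fbs`, `tg`, `hdl`.
#' @param sex `"male"`/`"female"`.
#' @param age years.
#' @param ref reference table from [read_reference_table()].
#' @return severity z-score (higher = worse).
#' @export
standardize_indicator <- function(value, indicator, sex, age,
                                  ref = read_reference_table()) {
  indicator <- match.arg(indicator, names(.INDICATOR_GROUP))
  row <- .ref_lookup(ref, sex, age_band(age), indicator)
  z <- (value - row$mean) / row$sd
  if (indicator == "hdl") -z else z
}

#' Assign the coaching management group
#'
#' The customized-coaching rule: a participant meeting no MS criterion is
#' managed in the `normal` group; otherwise each indicator whose
#' criterion is met is standardized against the sex/age reference and the
#' participant goes to the group owning the poorest (maximal-severity)
#' indicator — WC to obesity, SBP/DBP to blood_pressure, FBS to
#' blood_sugar, TG/HDL to lipid. Exact severity ties are broken by the
#' fixed priority obesity > blood_pressure > blood_sugar > lipid, so the
#' assignment is deterministic.
#'
#' @param sex,age participant sex and age.
#' @param wc,sbp,dbp,fbs,tg,hdl baseline measurements.
#' @param criteria named logical vector (or one-row data frame) of the
#'   five criterion flags from [evaluate_criteria()].
#' @param ref reference table.
#' @return one of `"obesity"`, `"blood_pressure"`, `"blood_sugar"`,
#'   `"lipid"`, `"normal"`.
#' @export
assign_management_group <- function(sex, age, wc, sbp, dbp, fbs, tg, hdl,
                                    criteria, ref = read_reference_table()) {
  criteria <- unlist(as.list(criteria)[MS_CRITERIA])
  if (!any(criteria)) return("normal")
  values <- c(wc = wc, sbp = sbp, dbp = dbp, fbs = fbs, tg = tg, hdl = hdl)
  active <- names(values)[criteria[.INDICATOR_CRITERION[names(values)]]]
  sev <- vapply(active, function(ind) {
    standardize_indicator(values[[ind]], ind, sex, age, ref)
  }, numeric(1))
  groups <- .INDICATOR_GROUP[active]
  # best severity per candidate group, then fixed-priority tie-break
  by_group <- vapply(unique(groups), function(g) max(sev[groups == g]), numeric(1))
  cand <- names(by_group)[by_group == max(by_group)]
  cand[order(match(cand, MANAGEMENT_GROUPS))][1]
}

#' Assign management groups across a cohort
#'
#' Applies [assign_management_group()] to each participant's baseline
#' (pre) row of a classified cohort and appends `management_group` to
#' every row of that participant.
#'
#' @param cohort cohort tibble already carrying the criterion flags (see
#'   [classify_cohort()]).
#' @param ref reference table.
#' @return the cohort with a `management_group` column appended.
#' @export
assign_cohort <- function(cohort, ref = read_reference_table()) {
  pre <- cohort[cohort$visit == "pre", ]
  grp <- vapply(seq_len(nrow(pre)), function(i) {
    assign_management_group(
      pre$sex[i], pre$age[i], pre$wc[i], pre$sbp[i], pre$dbp[i],
      pre$fbs[i], pre$tg[i], pre$hdl[i],
      criteria = pre[i, MS_CRITERIA], ref = ref)
  }, character(1))
  cohort$management_group <- factor(grp[match(cohort$id, pre$id)],
                                    levels = MANAGEMENT_GROUPS)
  cohort
}

#' Weekly coaching content schedule
#'
#' Three deliveries per week for every management group: Tuesday 14:00
#' nutrition/exercise/mental coaching, Thursday 14:00 general medical
#' knowledge, Sunday 09:00 the individualized weekly health report. The
#' cadence is identical across groups; only the content payload tag
#' differs (the normal group receives maintenance content).
#'
#' @param group management group label.
#' @param weeks number of weeks to schedule, default 1.
#' @return tibble with columns `week`, `weekday`, `time`, `kind`,
#'   `content_tag` (3 rows per week).
#' @export
content_schedule <- function(group, weeks = 1) {
  group <- match.arg(group, MANAGEMENT_GROUPS)
  tag <- if (group == "normal") "maintenance" else group
  base <- tibble(
    weekday = c("Tuesday", "Thursday", "Sunday"),
    time = c("14:00", "14:00", "09:00"),
    kind = c("nutrition_exercise_mental", "medical_knowledge", "weekly_report")
  )
  out <- dplyr::bind_rows(lapply(seq_len(weeks), function(w) {
    dplyr::mutate(base, week = w, .before = 1)
  }))
  out$content_tag <- tag
  out
}

#' Daily step target from the MSA stage
#'
#' A documented package convention (the deployed app's exact mapping is
#' unpublished): a monotone policy from stage to steps/day, default
#' good 8000, average 9000, poor 10000.
#'
#' @param stage MSA stage label(s), see [classify_msa_ca()].
#' @param policy named numeric vector keyed by stage.
#' @return steps/day, vectorized over `stage`.
#' @export
step_target <- function(stage,
                        policy = c(good = 8000, average = 9000, poor = 10000)) {
  stage <- as.character(stage)
  if (!all(stage %in% names(policy))) abort("policy must cover every stage", class = "msacoach_validation_error")
  unname(policy[stage])
}
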