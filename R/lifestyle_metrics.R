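SLEEP_LEVELS <- c("adequate_7_8", "inadequate")

#' Weekly ethanol intake in grams
#'
#' Drinking frequency times volume per occasion times alcohol content,
#' converted from ethanol volume to mass with the specific gravity of
#' alcohol (0.785 g/mL):
#' \deqn{g/week = freq \times mL \times pct \times 0.785 / 100}
#' Content is percent by volume entered as a number (4.5 for 4.5%).
#'
#' @param freq_per_week drinking occasions per week (>= 0).
#' @param amount_ml beverage volume per occasion, mL (>= 0).
#' @param content_pct alcohol content by volume, 0-100.
#' @return grams of ethanol per week; vectorized.
#' @export
weekly_alcohol_grams <- function(freq_per_week, amount_ml, content_pct) {
  if (any(freq_per_week < 0) || any(amount_ml < 0) || any(content_pct < 0)) {
    abort("drinking fields must be non-negative", class = "msacoach_validation_error")
  }
  if (any(content_pct > 100)) abort("alcohol content must be <= 100 percent", class = "msacoach_validation_error")
  freq_per_week * amount_ml * content_pct * 0.785 / 100
}

#' Sleep adequacy category
#'
#' Nightly sleep of 7-8 hours (closed interval) is adequate; shorter or
#' longer sleep is the combined inadequate category. The two categories
#' partition (0, 24).
#'
#' @param hours nightly sleep duration in (0, 24); vectorized.
#' @return factor with levels `adequate_7_8`, `inadequate`.
#' @export
categorize_sleep <- function(hours) {
  if (any(!is.finite(hours) | hours <= 0 | hours >= 24)) {
    abort("sleep_hours must lie in (0, 24)", class = "msacoach_validation_error")
  }
  factor(ifelse(hours >= 7 & hours <= 8, "adequate_7_8", "inadequate"),
         levels = SLEEP_LEVELS)
}

#' Mean daily steps over the first or last month of the study window
#'
#' A month is a 30-day window anchored at the participant's intervention
#' start (first month) or end (last month). Days with no record are
#' excluded from the denominator — non-wear is not zero activity.
#'
#' @param dates vector of `Date`s (one per recorded day).
#' @param steps daily step counts aligned with `dates`.
#' @param period `"first_month"` or `"last_month"`.
#' @param study_start,study_end `Date`s delimiting the study window.
#' @param window_days window length in days, default 30.
#' @return mean steps/day within the window, or `NA_real_` when the
#'   window holds no observations.
#' @export
mean_monthly_steps <- function(dates, steps, period = c("first_month", "last_month"),
                               study_start, study_end, window_days = 30) {
  period <- match.arg(period)
  stopifnot(length(dates) == length(steps))
  dates <- as.Date(dates)
  if (period == "first_month") {
    lo <- as.Date(study_start); hi <- lo + window_days - 1
  } else {
    hi <- as.Date(study_end); lo <- hi - window_days + 1
  }
  keep <- !is.na(steps) & dates >= lo & dates <= hi
  if (!any(keep)) return(NA_real_)
  mean(steps[keep])
}

#' Per-visit lifestyle summary
#'
#' Derives the analysis-ready lifestyle metrics from the raw lifestyle
#' fields of a cohort table: weekly ethanol grams and the sleep category,
#' appended as `alcohol_g_per_week` and `sleep_category`.
#'
#' @param cohort cohort tibble.
#' @return the cohort with the two derived columns appended.
#' @export
add_lifestyle_metrics <- function(cohort) {
  cohort$alcohol_g_per_week <- weekly_alcohol_grams(
    cohort$drink_freq_per_week, cohort$drink_amount_ml,
    cohort$alcohol_content_pct)
  cohort$sleep_category <- categorize_sleep(cohort$sleep_hours)
  cohort
}

#' Attach monthly step means from a daily series
#'
#' Long-format daily series (`id`, `date`, `steps`) -> per-visit
#' `steps_per_day`: the first-month mean feeds the pre row, the
#' last-month mean the post row.
#'
#' @param cohort cohort tibble.
#' @param steps long tibble with columns `id`, `date`, `steps`.
#' @param study_start,study_end study window `Date`s.
#' @param window_days window length, default 30.
#' @return the cohort with `steps_per_day` filled.
#' @export
add_step_means <- function(cohort, steps, study_start, study_end,
                           window_days = 30) {
  for (i in seq_len(nrow(cohort))) {
    s <- steps[steps$id == cohort$id[i], ]
    period <- if (cohort$visit[i] == "pre") "first_month" else "last_month"
    cohort$steps_per_day[i] <- mean_monthly_steps(
      s$date, s$steps, period, study_start, study_end, window_days)
  }
  cohort
}
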