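#' MS criterion thresholds
#'
#' The five harmonized metabolic-syndrome cutoffs with the Korean waist
#' conventions as shipped defaults: central obesity WC >= 90 cm (male) /
#' 85 cm (female); low HDL-C < 40 / < 50 mg/dL; triglycerides >= 150
#' mg/dL; blood pressure >= 130/85 mmHg; fasting glucose >= 100 mg/dL.
#' Thresholds are inclusive on the abnormal side (>= for upper cutoffs,
#' < for lower), matching guideline practice; `strict = TRUE` switches to
#' literal strict inequalities (> and <) for the upper cutoffs.
#'
#' @param wc_male,wc_female,hdl_male,hdl_female,tg,sbp,dbp,fbs cutoffs.
#' @param strict use strict inequalities at the upper cutoffs.
#' @return list of thresholds.
#' @export
ms_thresholds <- function(wc_male = 90, wc_female = 85, hdl_male = 40,
                          hdl_female = 50, tg = 150, sbp = 130, dbp = 85,
                          fbs = 100, strict = FALSE) {
  list(wc_male = wc_male, wc_female = wc_female, hdl_male = hdl_male,
       hdl_female = hdl_female, tg = tg, sbp = sbp, dbp = dbp, fbs = fbs,
       strict = strict)
}

MS_GROUP_LEVELS <- c("normal", "risk", "ms")
MS_CRITERIA <- c("obesity", "low_hdl", "high_tg", "hypertension", "hyperglycemia")

#' Evaluate the five MS criteria
#'
#' Vectorized over participants. Each "taking medication" flag dominates
#' the measured value for its criterion; lipid-lowering medication
#' triggers both lipid criteria (low HDL and high TG), since the criteria
#' attach medication without distinguishing drug class.
#'
#' @param sex `"male"`/`"female"`.
#' @param wc,sbp,dbp,fbs,tg,hdl measurements (cm, mmHg, mg/dL).
#' @param med_lipid,med_bp,med_glucose medication flags, default `FALSE`.
#' @param thresholds see [ms_thresholds()].
#' @return tibble of five logical columns, one row per participant:
#'   `obesity`, `low_hdl`, `high_tg`, `hypertension`, `hyperglycemia`.
#' @export
evaluate_criteria <- function(sex, wc, sbp, dbp, fbs, tg, hdl,
                              med_lipid = FALSE, med_bp = FALSE,
                              med_glucose = FALSE,
                              thresholds = ms_thresholds()) {
  if (!all(sex %in% SEX_LEVELS)) abort("sex must be 'male' or 'female'", class = "msacoach_validation_error")
  th <- thresholds
  ge <- if (isTRUE(th$strict)) `>` else `>=`
  wc_cut <- ifelse(sex == "male", th$wc_male, th$wc_female)
  hdl_cut <- ifelse(sex == "male", th$hdl_male, th$hdl_female)
  tibble(
    obesity = ge(wc, wc_cut),
    low_hdl = (hdl < hdl_cut) | med_lipid,
    high_tg = ge(tg, th$tg) | med_lipid,
    hypertension = ge(sbp, th$sbp) | ge(dbp, th$dbp) | med_bp,
    hyperglycemia = ge(fbs, th$fbs) | med_glucose
  )
}

#' Assign normal / risk / MS group from criterion flags
#'
#' Zero criteria met is the normal group, one or two the risk group,
#' three or more the MS group.
#'
#' @param criteria tibble or data frame of the five logical criterion
#'   columns (as from [evaluate_criteria()]).
#' @return tibble with `n_met` (0-5) and `group` (factor
#'   normal/risk/ms), one row per input row.
#' @export
classify_ms_group <- function(criteria) {
  criteria <- as_tibble(criteria)[, MS_CRITERIA]
  n_met <- as.integer(rowSums(criteria))
  group <- ifelse(n_met == 0, "normal", ifelse(n_met <= 2, "risk", "ms"))
  tibble(n_met = n_met, group = factor(group, levels = MS_GROUP_LEVELS))
}

#' Group counts and percentages
#'
#' @param groups factor/character vector of group labels (levels
#'   normal/risk/ms unless the input is already a factor with levels).
#' @param digits decimals for the percentage, default 1.
#' @return tibble with `group`, `n`, `pct`; counts sum to `length(groups)`.
#' @export
group_distribution <- function(groups, digits = 1) {
  if (!length(groups)) abort("empty cohort", class = "msacoach_validation_error")
  if (!is.factor(groups)) groups <- factor(groups, levels = MS_GROUP_LEVELS)
  tab <- table(groups)
  tibble(group = names(tab), n = as.integer(tab),
         pct = round_half_up(100 * as.integer(tab) / length(groups), digits))
}

#' Classify a cohort
#'
#' Appends the five criterion flags, `n_met` and `ms_group` to a
#' per-visit cohort table.
#'
#' @param cohort validated cohort tibble.
#' @param thresholds see [ms_thresholds()].
#' @return the cohort with seven columns appended.
#' @export
classify_cohort <- function(cohort, thresholds = ms_thresholds()) {
  crit <- evaluate_criteria(cohort$sex, cohort$wc, cohort$sbp, cohort$dbp,
                            cohort$fbs, cohort$tg, cohort$hdl,
                            cohort$med_lipid, cohort$med_bp,
                            cohort$med_glucose, thresholds)
  grp <- classify_ms_group(crit)
  names(grp)[names(grp) == "group"] <- "ms_group"
  dplyr::bind_cols(cohort, crit, grp)
}
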