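#' Default MSA coefficient sets
#'
#' The sex-specific linear model mapping biomarkers to Metabolic Syndrome
#' Age (MSA), in years:
#'
#' \deqn{MSA = b_0 + b_{WC} WC + b_{PP} PP + b_{FBS} FBS + b_{TG} TG +
#'   b_{HDL} HDL + b_{CA} CA}
#'
#' with waist circumference (cm), pulse pressure (mmHg), fasting blood
#' sugar, triglycerides and HDL-C (mg/dL) and chronological age (years).
#' The shipped defaults are the published big-data regression coefficients;
#' they are configuration data, not constants baked into the scorer, and a
#' revised set can be supplied via [load_msa_coefficients()].
#'
#' @return Named list with elements `male` and `female`, each a named
#'   numeric vector `(intercept, wc, pp, fbs, tg, hdl, ca)`.
#' @export
msa_coefficients <- function() {
  list(
    male = c(intercept = -82.688, wc = 0.779, pp = 0.227, fbs = 0.269,
             tg = 0.085, hdl = -0.481, ca = 0.857),
    female = c(intercept = -60.340, wc = 0.613, pp = 0.371, fbs = 0.328,
               tg = 0.100, hdl = -0.385, ca = 0.538)
  )
}

#' Load MSA coefficients from a YAML config file
#'
#' The file must have top-level keys `male` and `female`, each with the
#' seven coefficient names of [msa_coefficients()].
#'
#' @param path YAML file path.
#' @return Coefficient list in the shape of [msa_coefficients()].
#' @export
load_msa_coefficients <- function(path) {
  raw <- yaml::read_yaml(path)
  need <- c("intercept", "wc", "pp", "fbs", "tg", "hdl", "ca")
  out <- lapply(c(male = "male", female = "female"), function(sx) {
    v <- raw[[sx]]
    if (is.null(v) || !all(need %in% names(v))) {
      abort(paste0("coefficient file missing keys for ", sx),
            class = "msacoach_schema_error")
    }
    unlist(v)[need]
  })
  out
}

#' Pulse pressure
#'
#' The universal clinical definition: systolic minus diastolic blood
#' pressure, in mmHg.
#'
#' @param sbp,dbp blood pressures (mmHg), vectorized.
#' @return `sbp - dbp`.
#' @export
compute_pulse_pressure <- function(sbp, dbp) {
  if (any(!is.finite(sbp)) || any(!is.finite(dbp)) || any(dbp <= 0)) {
    abort("sbp and dbp must be finite with dbp > 0", class = "msacoach_validation_error")
  }
  if (any(sbp <= dbp)) abort("sbp > dbp violated", class = "msacoach_validation_error")
  sbp - dbp
}

#' Compute Metabolic Syndrome Age
#'
#' Evaluates the sex-specific linear MSA model. Pure arithmetic, no
#' rounding: presentation-layer rounding is left to report formatting so
#' staging never operates on truncated values. All arguments are
#' vectorized and recycled by the usual rules; `sex` selects the
#' coefficient row element-wise.
#'
#' @param sex `"male"`/`"female"`, vectorized.
#' @param wc waist circumference (cm).
#' @param sbp,dbp blood pressures (mmHg); pulse pressure is derived
#'   internally via [compute_pulse_pressure()].
#' @param fbs fasting blood sugar (mg/dL).
#' @param tg triglycerides (mg/dL).
#' @param hdl HDL cholesterol (mg/dL).
#' @param ca chronological age (years), > 0.
#' @param coefs coefficient sets, default [msa_coefficients()].
#' @return MSA in years.
#' @export
compute_msa <- function(sex, wc, sbp, dbp, fbs, tg, hdl, ca,
                        coefs = msa_coefficients()) {
  if (!all(sex %in% SEX_LEVELS)) abort("sex must be 'male' or 'female'", class = "msacoach_validation_error")
  if (any(ca <= 0)) abort("chronological age must be positive", class = "msacoach_validation_error")
  pp <- compute_pulse_pressure(sbp, dbp)
  n <- max(length(sex), length(wc), length(pp), length(fbs), length(tg),
           length(hdl), length(ca))
  X <- cbind(1, rep_len(wc, n), rep_len(pp, n), rep_len(fbs, n),
             rep_len(tg, n), rep_len(hdl, n), rep_len(ca, n))
  B <- rbind(coefs$male, coefs$female)[match(rep_len(sex, n), SEX_LEVELS), , drop = FALSE]
  rowSums(X * B)
}

#' Stage the MSA minus chronological-age difference
#'
#' Three-level staging of metabolic ageing relative to calendar age with a
#' symmetric one-year band: `good` when the participant is metabolically
#' more than `threshold` years younger than their CA (diff < -threshold),
#' `poor` when more than `threshold` years older (diff > +threshold), and
#' `average` in the closed band between. The band is closed at both ends so
#' the three stages partition the real line.
#'
#' @param diff MSA - CA, years (vectorized).
#' @param threshold half-width of the average band in years, default 1.
#' @return factor with levels `good`, `average`, `poor`.
#' @export
classify_msa_ca <- function(diff, threshold = 1.0) {
  if (any(!is.finite(diff))) abort("non-finite MSA-CA difference", class = "msacoach_validation_error")
  if (!is.numeric(threshold) || threshold <= 0) abort("threshold must be > 0", class = "msacoach_validation_error")
  stage <- ifelse(diff < -threshold, "good",
                  ifelse(diff > threshold, "poor", "average"))
  factor(stage, levels = MSA_STAGE_LEVELS)
}

#' @rdname classify_msa_ca
#' @format NULL
#' @export
MSA_STAGE_LEVELS <- c("good", "average", "poor")

#' Build an MSA result
#'
#' Bundles the score, the MSA - CA difference and its stage; the identity
#' `msa_ca_diff == msa - ca` is enforced by construction.
#'
#' @param msa MSA in years.
#' @param ca chronological age in years.
#' @param threshold staging band half-width, see [classify_msa_ca()].
#' @return tibble with `msa`, `msa_ca_diff`, `stage`.
#' @export
msa_result <- function(msa, ca, threshold = 1.0) {
  diff <- msa - ca
  tibble(msa = msa, msa_ca_diff = diff,
         stage = classify_msa_ca(diff, threshold))
}

#' Score a cohort
#'
#' Appends `msa`, `msa_ca_diff` and `msa_stage` columns to a per-visit
#' cohort table.
#'
#' @param cohort validated cohort tibble.
#' @param coefs coefficient sets, default [msa_coefficients()].
#' @param threshold staging band half-width (years).
#' @return the cohort with three columns appended.
#' @export
score_cohort <- function(cohort, coefs = msa_coefficients(), threshold = 1.0) {
  res <- msa_result(
    compute_msa(cohort$sex, cohort$wc, cohort$sbp, cohort$dbp, cohort$fbs,
                cohort$tg, cohort$hdl, cohort$age, coefs),
    cohort$age, threshold
  )
  cohort$msa <- res$msa
  cohort$msa_ca_diff <- res$msa_ca_diff
  cohort$msa_stage <- res$stage
  cohort
}
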