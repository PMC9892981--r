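#' Paired t test on aligned before/after vectors
#'
#' One-sample t on the differences `after - before`: statistic
#' `mean(d) / (sd(d)/sqrt(n))`, two-sided p from the t distribution with
#' n-1 degrees of freedom (delegated to [stats::t.test()]). Degenerate
#' zero-variance differences are handled explicitly rather than erroring:
#' a constant nonzero shift is reported with p = 0 and `degenerate =
#' TRUE`; identical vectors give statistic 0, p = 1.
#'
#' @param before,after numeric vectors aligned by participant, equal
#'   length >= 2, no missing values.
#' @return list of class `msacoach_test`: `test_name`, `statistic`, `df`,
#'   `p_value`, `degenerate`.
#' @export
paired_t_test <- function(before, after) {
  if (length(before) != length(after)) abort("before/after must align", class = "msacoach_validation_error")
  if (anyNA(before) || anyNA(after)) abort("missing values in paired sample", class = "msacoach_validation_error")
  n <- length(before)
  if (n < 2) abort("paired t test needs n >= 2", class = "msacoach_insufficient_data")
  d <- after - before
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      res <- list(test_name = "paired_t", statistic = 0, df = n - 1,
                  p_value = 1, degenerate = FALSE)
    } else {
      res <- list(test_name = "paired_t",
                  statistic = sign(mean(d)) * Inf, df = n - 1,
                  p_value = 0, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(after, before, paired = TRUE)
    res <- list(test_name = "paired_t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                degenerate = FALSE)
  }
  structure(res, class = "msacoach_test")
}

#' Chi-square homogeneity test on pre/post category counts
#'
#' Pearson chi-square on the 2 x k table (timepoint x category) with
#' expected counts from the margins, df = k - 1, two-sided p. This is
#' the plain chi-square a pre/post frequency table is usually given,
#' even though the timepoints are paired; see [mcnemar_prepost()] for
#' the paired alternative. No continuity correction by default.
#'
#' @param before_counts,after_counts named integer vectors over the same
#'   category set.
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return list of class `msacoach_test`: `test_name`, `statistic`, `df`,
#'   `p_value`, `small_expected` (`TRUE` when more than 20% of cells have
#'   expected count < 5; the test is still computed, with a warning).
#' @export
chi_square_prepost <- function(before_counts, after_counts, correct = FALSE) {
  if (is.null(names(before_counts)) || is.null(names(after_counts)) ||
      !setequal(names(before_counts), names(after_counts))) {
    abort("before/after counts must share one named category set", class = "msacoach_validation_error")
  }
  after_counts <- after_counts[names(before_counts)]
  if (sum(before_counts) == 0 || sum(after_counts) == 0) {
    abort("each timepoint needs a positive total", class = "msacoach_validation_error")
  }
  tab <- rbind(before = before_counts, after = after_counts)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) abort("expected count of zero (empty category)", class = "msacoach_validation_error")
  small <- mean(expected < 5) > 0.2
  if (small) warn("more than 20% of expected counts are below 5")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  structure(list(test_name = "chi_square", statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 small_expected = small),
            class = "msacoach_test")
}

#' McNemar test on paired pre/post categories (alternative)
#'
#' The statistically appropriate paired test for a two-timepoint nominal
#' variable, offered as an alternative to the homogeneity chi-square used
#' in the primary report.
#'
#' @param before,after factors/character vectors aligned by participant.
#' @param correct continuity correction, default `TRUE` (the
#'   [stats::mcnemar.test()] default).
#' @return list of class `msacoach_test`.
#' @export
mcnemar_prepost <- function(before, after, correct = TRUE) {
  if (length(before) != length(after)) abort("before/after must align", class = "msacoach_validation_error")
  levels_all <- union(unique(as.character(before)), unique(as.character(after)))
  tab <- table(factor(before, levels_all), factor(after, levels_all))
  mt <- stats::mcnemar.test(tab, correct = correct)
  structure(list(test_name = "mcnemar", statistic = unname(mt$statistic),
                 df = unname(mt$parameter), p_value = mt$p.value),
            class = "msacoach_test")
}

#' @export
print.msacoach_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %g, p = %.4g\n",
              x$test_name, x$statistic, x$df, x$p_value))
  invisible(x)
}

.continuous_row <- function(cohort, var, label, section) {
  pv <- paired_values(cohort, var)
  tt <- paired_t_test(pv$before, pv$after)
  tibble(section = section, label = label,
         before = fmt_mean_sd(pv$before), after = fmt_mean_sd(pv$after),
         p_value = tt$p_value, p = fmt_p(tt$p_value))
}

.nominal_block <- function(cohort, var, label, section, levels_order = NULL) {
  pv <- paired_values(cohort, var)
  before <- as.character(pv$before); after <- as.character(pv$after)
  lev <- levels_order %||% sort(unique(c(before, after)))
  bc <- table(factor(before, lev)); ac <- table(factor(after, lev))
  # categories empty at both timepoints carry no information and would
  # zero an expected count; drop them from the test (they stay displayed)
  occupied <- as.integer(bc) + as.integer(ac) > 0
  pval <- if (sum(occupied) >= 2) {
    suppressWarnings(
      chi_square_prepost(stats::setNames(as.integer(bc)[occupied], lev[occupied]),
                         stats::setNames(as.integer(ac)[occupied], lev[occupied]))
    )$p_value
  } else NA_real_
  header <- tibble(section = section, label = label, before = "", after = "",
                   p_value = pval, p = ifelse(is.na(pval), "", fmt_p(pval)))
  n_b <- sum(bc); n_a <- sum(ac)
  rows <- tibble(
    section = section, label = paste0("  ", lev),
    before = vapply(lev, function(l) fmt_n_pct(bc[[l]], n_b), character(1)),
    after = vapply(lev, function(l) fmt_n_pct(ac[[l]], n_a), character(1)),
    p_value = NA_real_, p = "")
  dplyr::bind_rows(header, rows)
}

#' Build the pre/post comparison report
#'
#' Assembles the publication-shaped before/after tables from a scored,
#' classified cohort with lifestyle metrics attached: the clinical
#' indicators block (8 continuous rows, paired t), the MS block (MSA-CA
#' mean row plus the stage and group distributions, chi-square), and the
#' lifestyle block (exercise, smoking, drinking, weekly ethanol grams,
#' sleep category, stress, step counts, diet). Continuous cells are
#' "mean (SD)" to 2 decimals, nominal cells "n (pct)" with the
#' percentage to 1 decimal, p-values 2 decimals with the leading zero
#' dropped. Participants missing the post visit are excluded
#' (complete-case), with the exclusion count attached as an attribute.
#'
#' @param cohort per-visit cohort tibble already carrying `msa_ca_diff`,
#'   `msa_stage`, `ms_group` (see [score_cohort()], [classify_cohort()]);
#'   lifestyle metrics are derived internally if absent.
#' @param sections which blocks to build, subset of
#'   `c("clinical", "ms", "lifestyle")`.
#' @return tibble with columns `section`, `label`, `before`, `after`,
#'   `p_value` (numeric, `NA` on nominal level rows), `p` (formatted);
#'   attribute `n_analysis` (paired n) and `n_excluded`.
#' @export
build_prepost_report <- function(cohort,
                                 sections = c("clinical", "ms", "lifestyle")) {
  sections <- match.arg(sections, several.ok = TRUE)
  if (!"alcohol_g_per_week" %in% names(cohort)) cohort <- add_lifestyle_metrics(cohort)
  ids_pre <- cohort$id[cohort$visit == "pre"]
  ids_post <- cohort$id[cohort$visit == "post"]
  complete <- intersect(ids_pre, ids_post)
  n_excluded <- length(setdiff(ids_pre, ids_post))
  if (n_excluded > 0) {
    message(n_excluded, " participant(s) without a post visit excluded from the analysis set")
  }
  cohort <- cohort[cohort$id %in% complete, ]

  out <- list()
  if ("clinical" %in% sections) {
    clin <- list(height = "Height (cm)", weight = "Weight (kg)",
                 wc = "Waist circumference (cm)",
                 sbp = "Systolic blood pressure (mmHg)",
                 dbp = "Diastolic blood pressure (mmHg)",
                 fbs = "Fasting blood sugar (mg/dL)",
                 tg = "Triglycerides (mg/dL)",
                 hdl = "HDL cholesterol (mg/dL)")
    out <- c(out, lapply(names(clin), function(v)
      .continuous_row(cohort, v, clin[[v]], "clinical")))
  }
  if ("ms" %in% sections) {
    out <- c(out, list(
      .continuous_row(cohort, "msa_ca_diff", "MSA-CA (years), mean (SD)", "ms"),
      .nominal_block(cohort, "msa_stage", "Classification by MSA-CA", "ms",
                     MSA_STAGE_LEVELS),
      .nominal_block(cohort, "ms_group", "Type of MS", "ms", MS_GROUP_LEVELS)))
  }
  if ("lifestyle" %in% sections) {
    out <- c(out, list(
      .continuous_row(cohort, "exercise_per_week", "The number of exercises, mean (SD)", "lifestyle"),
      .nominal_block(cohort, "smoking", "Smoking state, n (%)", "lifestyle", SMOKING_LEVELS),
      .nominal_block(cohort, "drinking", "Drinking state, n (%)", "lifestyle", DRINKING_LEVELS),
      .continuous_row(cohort, "alcohol_g_per_week", "Alcohol consumption per week (g/w), mean (SD)", "lifestyle"),
      .nominal_block(cohort, "sleep_category", "Sleeping time, n (%)", "lifestyle", SLEEP_LEVELS),
      .continuous_row(cohort, "stress", "Stress score, mean (SD)", "lifestyle"),
      .continuous_row(cohort, "steps_per_day", "Step counts, mean (SD)", "lifestyle"),
      .nominal_block(cohort, "diet", "Eating habit, n (%)", "lifestyle", DIET_LEVELS)))
  }
  report <- dplyr::bind_rows(out)
  attr(report, "n_analysis") <- length(complete)
  attr(report, "n_excluded") <- n_excluded
  report
}

#' Render a report as aligned plain text
#'
#' @param report tibble from [build_prepost_report()].
#' @return character vector of lines, invisibly; also printed.
#' @export
format_report_text <- function(report) {
  w1 <- max(nchar(report$label), nchar("Parameter"))
  w2 <- max(nchar(report$before), nchar("Before"))
  w3 <- max(nchar(report$after), nchar("After"))
  lines <- c(
    sprintf("%-*s  %*s  %*s  %s", w1, "Parameter", w2, "Before", w3, "After", "P value"),
    sprintf("%-*s  %*s  %*s  %s", w1, report$label, w2, report$before,
            w3, report$after, report$p))
  cat(lines, sep = "\n")
  invisible(lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
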