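# Small cohorts built in code for the I/O and analysis tests.

# One participant, both visits, hand-picked healthy values.
make_minimal_cohort <- function() {
  tibble::tibble(
    id = c("A1", "A1"), visit = c("pre", "post"),
    sex = "male", age = 45,
    med_lipid = FALSE, med_bp = FALSE, med_glucose = FALSE,
    height = 175, weight = 72, wc = c(82, 81), sbp = c(118, 117),
    dbp = c(76, 75), fbs = c(92, 90), tg = c(110, 105), hdl = c(52, 53),
    exercise_per_week = c(3, 4), smoking = "nonsmoker",
    drinking = c("nondrinker", "nondrinker"),
    drink_freq_per_week = 0, drink_amount_ml = 0, alcohol_content_pct = 0,
    sleep_hours = c(6.5, 7.5), stress = c(3L, 2L), diet = c("bad", "good"),
    steps_per_day = c(5400, 6100)
  )
}

# n participants with both visits, randomized but validate-clean.
make_random_cohort <- function(n, seed = 99) {
  cfg <- cohort_config(n = n)
  co <- generate_baseline(cfg, seed = seed, n = n)
  apply_intervention(co, cfg$effect, seed = seed + 1, config = cfg)
}
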