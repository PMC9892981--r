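cfg <- cohort_config()

test_that("truncated-normal matching undoes truncation bias exactly", {
  ind <- cfg$indicators
  for (i in seq_len(nrow(ind))) {
    mom <- msacoach:::.tnorm_moments(ind$mu[i], ind$sigma[i],
                                     ind$lower[i], ind$upper[i])
    expect_equal(unname(mom["mean"]), ind$mean[i], tolerance = 1e-4)
    expect_equal(unname(mom["sd"]), ind$sd[i], tolerance = 1e-3)
  }
})

test_that("generation is deterministic given (config, seed)", {
  a <- generate_baseline(cfg, seed = 3, n = 50)
  b <- generate_baseline(cfg, seed = 3, n = 50)
  expect_identical(a, b)
  c <- generate_baseline(cfg, seed = 4, n = 50)
  expect_false(identical(a$wc, c$wc))

  g1 <- generate_cohort(cfg, seed = 11)
  g2 <- generate_cohort(cfg, seed = 11)
  expect_identical(as.data.frame(g1), as.data.frame(g2))
})

test_that("the sex split is deterministic at the trial composition", {
  co <- generate_baseline(cfg, seed = 2, n = 63)
  expect_equal(sum(co$sex == "male"), 30)
  expect_equal(sum(co$sex == "female"), 33)
})

test_that("baseline cohorts pass validation", {
  co <- generate_baseline(cfg, seed = 6, n = 200)
  expect_silent(validate_cohort(co))
})

test_that("large-sample marginals recover the configured moments", {
  co <- generate_baseline(cfg, seed = 123, n = 20000)
  ind <- cfg$indicators
  for (i in seq_len(nrow(ind))) {
    v <- co[[ind$indicator[i]]]
    expect_lt(abs(mean(v) - ind$mean[i]) / ind$mean[i], 0.02)
    expect_lt(abs(sd(v) - ind$sd[i]) / ind$sd[i], 0.05)
  }
  expect_lt(abs(mean(co$age) - 47.61) / 47.61, 0.02)
  expect_lt(abs(mean(co$steps_per_day) - 6425) / 6425, 0.02)
})

test_that("the copula induces the intended dependence directions", {
  co <- generate_baseline(cfg, seed = 31, n = 20000)
  expect_gt(cor(co$wc, co$tg), 0.2)
  expect_gt(cor(co$sbp, co$dbp), 0.5)
  expect_lt(cor(co$tg, co$hdl), -0.3)
})

test_that("a zero-effect specification leaves the post visit identical", {
  base <- generate_baseline(cfg, seed = 9, n = 30)
  both <- apply_intervention(base, zero_effect_spec(), seed = 10, config = cfg)
  pre <- both[both$visit == "pre", ]
  post <- both[both$visit == "post", ]
  for (v in setdiff(names(pre), "visit")) {
    expect_equal(post[[v]], pre[[v]], info = v)
  }
})

test_that("the default effect recovers the printed deltas in expectation", {
  base <- generate_baseline(cfg, seed = 14, n = 20000)
  both <- apply_intervention(base, cfg$effect, seed = 15, config = cfg)
  pre <- both[both$visit == "pre", ]; post <- both[both$visit == "post", ]
  expect_equal(mean(post$tg) - mean(pre$tg), -20.49, tolerance = 0.1)    # relative
  expect_equal(mean(post$steps_per_day) - mean(pre$steps_per_day), 203,
               tolerance = 0.1)
  expect_lt(abs((mean(post$wc) - mean(pre$wc)) - (-0.31)), 0.1)
  # categorical transitions move the expected fractions
  expect_lt(mean(post$smoking == "current_smoker"),
            mean(pre$smoking == "current_smoker"))
  expect_gt(mean(categorize_sleep(post$sleep_hours) == "adequate_7_8"),
            mean(categorize_sleep(pre$sleep_hours) == "adequate_7_8"))
})

test_that("attrition removes the specified counts and conserves enrollment", {
  att <- simulate_attrition(attrition_spec(), seed = 1)
  expect_equal(att$analysis_n, 63)
  expect_equal(att$log$n_remaining, c(215, 170, 109, 69, 63))

  none <- simulate_attrition(attrition_spec(100, 0, 0, 0, 0), seed = 2)
  expect_equal(none$analysis_n, 100)

  set.seed(44)
  for (i in 1:10) {
    n0 <- sample(50:300, 1)
    parts <- rmultinom(1, sample(0:(n0 - 1), 1), rep(1, 4))[, 1]
    spec <- attrition_spec(n0, parts[1], parts[2], parts[3], parts[4])
    att <- simulate_attrition(spec, seed = i)
    expect_equal(att$analysis_n, n0 - sum(parts))
    expect_equal(att$analysis_n + length(unlist(att$removed)), n0)
  }
  expect_error(attrition_spec(100, 60, 30, 20, 5), class = "msacoach_config_error")
})

test_that("generate_cohort yields the 63-participant complete-case analysis set", {
  co <- generate_cohort(cfg, seed = 5)
  expect_equal(length(unique(co$id)), 63)
  expect_equal(nrow(co), 126)
  expect_equal(sort(unique(table(co$id))), 2)

  full <- generate_cohort(cfg, seed = 5, include_dropouts = TRUE)
  expect_equal(length(unique(full$id)), 170)   # eligible after screening
  expect_equal(sum(full$visit == "post"), 63)  # only the analysis set has post
  log <- attr(full, "attrition_log")
  expect_equal(log$n_remaining[1] - sum(log$n_removed), 63)
})

test_that("scoring plus classification on default cohorts brackets the trial's group mix", {
  # distributional check at large n: proportions near normal/risk/MS 21/51/29
  co <- generate_baseline(cfg, seed = 20, n = 20000)
  d <- group_distribution(classify_cohort(co)$ms_group)
  expect_lt(abs(d$pct[d$group == "normal"] - 20.6), 10)
  expect_lt(abs(d$pct[d$group == "risk"] - 50.8), 10)
  expect_lt(abs(d$pct[d$group == "ms"] - 28.6), 10)
})

test_that("infeasible truncation is a configuration error", {
  expect_error(msacoach:::.match_truncnorm(100, 200, 95, 105),
               class = "msacoach_config_error")
})
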