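ref <- read_reference_table()

test_that("severity standardization centers, scales and flips HDL", {
  m <- ref[ref$sex == "male" & ref$age_band == "40-49", ]
  wc_row <- m[m$indicator == "wc", ]
  expect_equal(standardize_indicator(wc_row$mean, "wc", "male", 45, ref), 0)
  expect_equal(standardize_indicator(wc_row$mean + wc_row$sd, "wc", "male", 45, ref), 1)
  hdl_row <- m[m$indicator == "hdl", ]
  expect_equal(standardize_indicator(hdl_row$mean + hdl_row$sd, "hdl", "male", 45, ref), -1)
})

test_that("severity is invariant under affine re-expression of units", {
  set.seed(31)
  ref2 <- ref
  # re-express wc rows in, say, millimetres: x -> 10x (+ offset for generality)
  sel <- ref2$indicator == "wc"
  ref2$mean[sel] <- 10 * ref2$mean[sel] + 3
  ref2$sd[sel] <- 10 * ref2$sd[sel]
  for (i in 1:10) {
    v <- runif(1, 60, 110); age <- runif(1, 22, 78)
    expect_equal(standardize_indicator(10 * v + 3, "wc", "female", age, ref2),
                 standardize_indicator(v, "wc", "female", age, ref))
  }
})

test_that("age bands tile ages 20+ and missing strata error", {
  expect_equal(age_band(c(20, 29.9, 30, 47, 69.9, 70, 85)),
               c("20-29", "20-29", "30-39", "40-49", "60-69", "70+", "70+"))
  expect_error(age_band(19), class = "msacoach_reference_error")
  expect_error(standardize_indicator(80, "wc", "male", 45, ref[0, ]),
               class = "msacoach_reference_error")
})

no_crit <- stats::setNames(rep(FALSE, 5),
  c("obesity", "low_hdl", "high_tg", "hypertension", "hyperglycemia"))

test_that("no criteria met is managed in the normal group", {
  expect_equal(assign_management_group("male", 45, 80, 118, 75, 90, 100, 55,
                                       criteria = no_crit, ref = ref),
               "normal")
})

test_that("the group of the poorest met indicator wins", {
  # only obesity met, clearly elevated WC
  crit <- no_crit; crit["obesity"] <- TRUE
  expect_equal(assign_management_group("male", 45, wc = 104, sbp = 118, dbp = 75,
                                       fbs = 90, tg = 100, hdl = 55,
                                       criteria = crit, ref = ref),
               "obesity")

  # hypertension and hyperglycemia met; FBS further above its stratum
  crit <- no_crit; crit[c("hypertension", "hyperglycemia")] <- TRUE
  m <- ref[ref$sex == "male" & ref$age_band == "40-49", ]
  sbp_v <- m$mean[m$indicator == "sbp"] + 1.2 * m$sd[m$indicator == "sbp"]
  dbp_v <- m$mean[m$indicator == "dbp"] + 0.4 * m$sd[m$indicator == "dbp"]
  fbs_v <- m$mean[m$indicator == "fbs"] + 1.9 * m$sd[m$indicator == "fbs"]
  expect_equal(assign_management_group("male", 45, wc = 95, sbp = sbp_v,
                                       dbp = dbp_v, fbs = fbs_v, tg = 160,
                                       hdl = 55, criteria = crit, ref = ref),
               "blood_sugar")

  # unmet criteria never compete, however extreme the raw value
  crit <- no_crit; crit["low_hdl"] <- TRUE
  expect_equal(assign_management_group("female", 52, wc = 120, sbp = 112,
                                       dbp = 70, fbs = 85, tg = 90, hdl = 30,
                                       criteria = crit, ref = ref),
               "lipid")
})

test_that("exact severity ties break by fixed priority", {
  # craft equal z for wc and sbp, both criteria met
  f <- ref[ref$sex == "female" & ref$age_band == "50-59", ]
  z <- 2
  wc_v <- f$mean[f$indicator == "wc"] + z * f$sd[f$indicator == "wc"]
  sbp_v <- f$mean[f$indicator == "sbp"] + z * f$sd[f$indicator == "sbp"]
  crit <- no_crit; crit[c("obesity", "hypertension")] <- TRUE
  expect_equal(assign_management_group("female", 55, wc = wc_v, sbp = sbp_v,
                                       dbp = 70, fbs = 90, tg = 100, hdl = 60,
                                       criteria = crit, ref = ref),
               "obesity")
})

test_that("cohort assignment is deterministic and normal iff zero criteria", {
  co <- classify_cohort(make_random_cohort(40))
  a1 <- assign_cohort(co, ref)
  a2 <- assign_cohort(co, ref)
  expect_identical(a1$management_group, a2$management_group)
  pre <- a1[a1$visit == "pre", ]
  expect_equal(pre$management_group == "normal", pre$n_met == 0)
})

test_that("the weekly schedule has the three fixed deliveries", {
  s <- content_schedule("obesity")
  expect_equal(nrow(s), 3)
  expect_equal(s$weekday, c("Tuesday", "Thursday", "Sunday"))
  expect_equal(s$time, c("14:00", "14:00", "09:00"))
  expect_equal(s$kind, c("nutrition_exercise_mental", "medical_knowledge",
                         "weekly_report"))
  expect_equal(nrow(content_schedule("lipid", weeks = 2)), 6)
  n <- content_schedule("normal")
  expect_equal(n[, c("weekday", "time", "kind")], s[, c("weekday", "time", "kind")])
  expect_equal(unique(n$content_tag), "maintenance")
})

test_that("step targets follow the stage policy", {
  expect_equal(step_target("good"), 8000)
  expect_equal(step_target("poor"), 10000)
  expect_equal(step_target(c("good", "average", "poor"),
                           policy = c(good = 7000, average = 7000, poor = 7000)),
               rep(7000, 3))
})
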