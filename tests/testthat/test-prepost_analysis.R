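# Independent textbook oracles, kept free of the implementation path.
oracle_paired_t <- function(before, after) {
  d <- after - before
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}
oracle_chisq <- function(before, after) {
  tab <- rbind(before, after)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- 0
  for (i in 1:2) for (j in seq_len(ncol(tab))) {
    stat <- stat + (tab[i, j] - E[i, j])^2 / E[i, j]
  }
  df <- ncol(tab) - 1
  stat <- unname(stat)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

test_that("paired t equals the one-sample-t-on-differences oracle", {
  before <- c(10, 12, 9, 11, 13); after <- c(11, 11, 10, 13, 14)
  got <- paired_t_test(before, after)
  exp <- oracle_paired_t(before, after)
  expect_equal(got$statistic, exp$statistic, tolerance = 1e-12)
  expect_equal(got$df, exp$df)
  expect_equal(got$p_value, exp$p, tolerance = 1e-12)

  set.seed(77)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    b <- rnorm(n, 100, 15); a <- b + rnorm(n, 1, 4)
    got <- paired_t_test(b, a); exp <- oracle_paired_t(b, a)
    expect_equal(got$statistic, exp$statistic, tolerance = 1e-9)
    expect_equal(got$p_value, exp$p, tolerance = 1e-9)
  }
})

test_that("paired t handles identical and degenerate samples", {
  x <- c(3, 5, 9, 4)
  same <- paired_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$degenerate)

  const <- paired_t_test(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_true(const$degenerate)
  expect_equal(const$p_value, 0)

  expect_error(paired_t_test(1, 2), class = "msacoach_insufficient_data")
  expect_error(paired_t_test(1:3, 1:4), class = "msacoach_validation_error")
})

test_that("swapping before and after negates the statistic and keeps p", {
  set.seed(13)
  for (i in 1:20) {
    b <- rnorm(12); a <- b + rnorm(12, 0.5)
    f <- paired_t_test(b, a); r <- paired_t_test(a, b)
    expect_equal(r$statistic, -f$statistic, tolerance = 1e-12)
    expect_equal(r$p_value, f$p_value, tolerance = 1e-12)
  }
})

test_that("chi-square equals the O/E oracle, including the printed sleep table", {
  before <- c(inadequate = 47, adequate_7_8 = 16)
  after <- c(inadequate = 37, adequate_7_8 = 26)
  got <- chi_square_prepost(before, after)
  exp <- oracle_chisq(unname(before), unname(after))
  expect_equal(got$statistic, exp$statistic, tolerance = 1e-9)
  expect_equal(got$df, 1)
  expect_equal(got$p_value, exp$p, tolerance = 1e-9)

  set.seed(23)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    b <- rpois(k, 20) + 1; a <- rpois(k, 20) + 1
    names(b) <- names(a) <- letters[seq_len(k)]
    got <- suppressWarnings(chi_square_prepost(b, a))
    exp <- oracle_chisq(unname(b), unname(a))
    expect_equal(got$statistic, exp$statistic, tolerance = 1e-9)
    expect_equal(got$p_value, exp$p, tolerance = 1e-9)
  }
})

test_that("chi-square is invariant to category order and flags small cells", {
  b <- c(x = 30, y = 20, z = 10); a <- c(x = 25, y = 22, z = 13)
  g1 <- chi_square_prepost(b, a)
  g2 <- chi_square_prepost(b[c(3, 1, 2)], a)   # names realign the categories
  expect_equal(g1$statistic, g2$statistic, tolerance = 1e-12)

  expect_equal(chi_square_prepost(c(m = 30, f = 33), c(m = 30, f = 33))$statistic, 0)

  expect_warning(chi_square_prepost(c(a = 2, b = 50), c(a = 3, b = 49)),
                 "expected")
  expect_error(chi_square_prepost(c(a = 0, b = 10), c(a = 0, b = 12)),
               class = "msacoach_validation_error")
  expect_error(chi_square_prepost(c(a = 1), c(b = 1)),
               class = "msacoach_validation_error")
})

test_that("mcnemar alternative runs on paired categories", {
  set.seed(9)
  b <- sample(c("good", "bad"), 60, TRUE)
  a <- ifelse(runif(60) < 0.2, "good", b)
  got <- mcnemar_prepost(b, a)
  expect_equal(got$test_name, "mcnemar")
  expect_true(got$p_value >= 0 && got$p_value <= 1)
})

test_that("the report has the publication layout and formatting", {
  co <- make_random_cohort(63, seed = 5)
  sc <- add_lifestyle_metrics(classify_cohort(score_cohort(co)))
  rep <- build_prepost_report(sc)

  expect_equal(sum(rep$section == "clinical"), 8)
  # two nominal blocks (3 levels each + header) plus the mean row
  expect_equal(sum(rep$section == "ms"), 1 + 4 + 4)
  # lifestyle: 4 continuous rows + 4 two-level blocks of 3 rows
  expect_equal(sum(rep$section == "lifestyle"), 4 + 4 * 3)
  expect_equal(attr(rep, "n_analysis"), 63)

  # nominal level rows: counts sum to n, percentages to ~100
  lev <- rep[grepl("^  ", rep$label) & rep$section == "ms", ]
  n <- vapply(lev$before, function(s) as.integer(sub(" .*", "", s)), integer(1))
  expect_equal(sum(n[1:3]), 63)
  pct <- vapply(lev$before, function(s)
    as.numeric(sub(".*\\((.*)\\)", "\\1", s)), numeric(1))
  expect_lt(abs(sum(pct[1:3]) - 100), 0.3)

  # mean (SD) and p-value formatting
  expect_match(rep$before[rep$label == "Height (cm)"],
               "^\\d+\\.\\d{2} \\(\\d+\\.\\d{2}\\)$")
  expect_true(all(grepl("^($|1\\.00|<?\\.\\d{2})$", rep$p)))
})

test_that("printed count cells reproduce the n (pct) convention", {
  groups_pre <- factor(c(rep("normal", 13), rep("risk", 32), rep("ms", 18)),
                       levels = c("normal", "risk", "ms"))
  d <- group_distribution(groups_pre)
  cells <- sprintf("%d (%.1f)", d$n, d$pct)
  expect_equal(cells, c("13 (20.6)", "32 (50.8)", "18 (28.6)"))
})

test_that("a no-change cohort reports p = 1.00 everywhere it can", {
  co <- make_random_cohort(20, seed = 8)
  pre <- co[co$visit == "pre", ]
  post <- pre; post$visit <- "post"
  sc <- add_lifestyle_metrics(classify_cohort(score_cohort(
    dplyr::bind_rows(pre, post))))
  rep <- build_prepost_report(sc)
  # continuous rows with nonconstant differences and all nominal blocks
  expect_true(all(rep$p[!is.na(rep$p_value)] == "1.00"))
})

test_that("participants missing the post visit are excluded with a message", {
  co <- make_random_cohort(10, seed = 3)
  co <- co[!(co$visit == "post" & co$id %in% unique(co$id)[1:2]), ]
  sc <- add_lifestyle_metrics(classify_cohort(score_cohort(co)))
  expect_message(rep <- build_prepost_report(sc), "2 participant")
  expect_equal(attr(rep, "n_analysis"), 8)
  expect_equal(attr(rep, "n_excluded"), 2)
})
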