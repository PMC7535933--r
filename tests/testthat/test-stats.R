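test_that("two-sample t matches the pooled-variance closed form", {
  same <- ttest_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- ttest_two_sample(c(1, 2, 3), c(2, 3, 4))
  # pooled s^2 = 1, SE = sqrt(2/3), t = -1 / sqrt(2/3)
  expect_equal(res$statistic, -1 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(res$statistic, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)

  degen <- ttest_two_sample(c(2, 2), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  w <- ttest_two_sample(c(1, 2, 3, 9), c(2, 3, 4), variant = "welch")
  expect_equal(w$test, "t_welch")
})

test_that("uncorrected chi-square equals its closed form on integer tables", {
  flat <- chisq_2x2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  tab <- matrix(c(9, 6, 6, 33), 2, 2, byrow = TRUE)
  res <- chisq_2x2(tab)
  a <- 9; b <- 6; cc <- 6; d <- 33; N <- 54
  closed <- N * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(res$statistic, closed, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(closed, 1, lower.tail = FALSE))

  # reference quantile of the chi-square distribution at df = 1
  near <- chisq_2x2(matrix(c(24, 11, 11, 24), 2, 2))  # statistic near 3.84
  expect_equal(near$p_value,
               stats::pchisq(near$statistic, 1, lower.tail = FALSE))
  expect_error(chisq_2x2(matrix(c(5, 0, 7, 0), 2, 2)), "marginal")
})

test_that("one-way ANOVA matches hand sums of squares and t^2 on 2 groups", {
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  res <- anova_oneway(list(c(1, 2), c(3, 4)))
  expect_equal(res$statistic, 8)      # SSB = 4, SSW = 1, df = (1, 2)
  expect_equal(res$df, 1)
  expect_equal(res$df2, 2)

  a <- c(1.2, 2.3, 3.1, 0.8); b <- c(2.2, 3.5, 4.1)
  f <- anova_oneway(list(a, b))
  t <- ttest_two_sample(a, b)
  expect_equal(f$statistic, t$statistic^2, tolerance = 1e-10)
  expect_equal(f$p_value, t$p_value, tolerance = 1e-10)
})

test_that("the t-test holds its nominal type-I error rate", {
  n <- 30; reps <- 10000
  rej <- withr::with_seed(77, {
    a <- matrix(stats::rnorm(n * reps), n)
    b <- matrix(stats::rnorm(n * reps), n)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- colSums((a - rep(ma, each = n))^2) / (n - 1)
    vb <- colSums((b - rep(mb, each = n))^2) / (n - 1)
    s2 <- ((n - 1) * va + (n - 1) * vb) / (2 * n - 2)
    tstat <- (ma - mb) / sqrt(s2 * 2 / n)
    p <- 2 * stats::pt(-abs(tstat), 2 * n - 2)
    mean(p < 0.05)
  })
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("percentages print one decimal, rounded half up", {
  expect_equal(percent_of(17, 28), 60.7)
  expect_equal(percent_of(10, 50), 20.0)
  expect_equal(percent_of(33, 39), 84.6)
  expect_equal(percent_of(1, 16), 6.3)    # 6.25 rounds half up
})

test_that("cohort reports build contingency tables with both tests", {
  cells <- tibble::tibble(
    condition = rep(c("early_cre", "late_cre"), c(15, 39)),
    mode = c(rep("direct", 9), rep("reversal", 6),
             rep("direct", 6), rep("reversal", 33))
  )
  rep1 <- cohort_report(cells)
  expect_equal(unname(rep1$contingency["early_cre", "reversal"]), 6L)
  chi <- rep1$tests[rep1$tests$test == "chisq_none", ]
  expect_equal(round(chi$p_value, 4), 0.0010)
  expect_true("fisher_exact" %in% rep1$tests$test)
  pct <- rep1$percentages
  expect_equal(pct$percent[pct$condition == "late_cre" &
                             pct$mode == "reversal"], 84.6)

  empty <- cohort_report(tibble::tibble())
  expect_equal(nrow(empty$cells), 0L)
  expect_null(empty$contingency)
})

test_that("report files regenerate bit-identically", {
  cells <- tibble::tibble(
    condition = rep(c("a", "b"), each = 6),
    mode = rep(c("direct", "reversal"), 6),
    latency_hr = seq(8, 13.5, by = 0.5)
  )
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cohort_report(cells, out_dir = d1, params = list(seed = 1))
  cohort_report(cells, out_dir = d2, params = list(seed = 1))
  for (f in c("cells.csv", "report.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("tidy and glance expose broom-style summaries", {
  td <- generics::tidy(ttest_two_sample(c(1, 2, 3), c(2, 3, 4)))
  expect_named(td, c("statistic", "parameter", "p.value", "method"))
  truth <- simulate_cell(sim_params(), seed = 2, n_frames = 90)
  an <- analyze_cell_truth(truth)
  g <- generics::glance(an)
  expect_equal(nrow(g), 1L)
  expect_true(all(c("mode", "phase2_entry", "mean_d_xy_II") %in% names(g)))
  expect_s3_class(generics::tidy(an), "tbl_df")
})
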