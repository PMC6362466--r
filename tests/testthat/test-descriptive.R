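test_that("risk ratio and log-Wald CI reproduce published registry rows", {
  # stage II (2796/6353) vs in situ (1439/5451)
  rr <- risk_ratio(2796, 6353, 1439, 5451)
  expect_equal(round(rr$rr, 1), 1.7)
  expect_equal(round(rr$ci_low, 1), 1.6)
  expect_equal(round(rr$ci_high, 1), 1.8)
  # size 5.0+ (1280/2043) vs 0.0-0.9 (1271/5236)
  expect_equal(round(risk_ratio(1280, 2043, 1271, 5236)$rr, 1), 2.6)
  # age 50-64 (3519/10284) vs 40-49 (1956/4392)
  expect_equal(round(risk_ratio(3519, 10284, 1956, 4392)$rr, 1), 0.8)
  # identical proportions give RR 1
  expect_equal(risk_ratio(10, 100, 10, 100)$rr, 1)
  # zero reference events flag the CI undefined
  expect_true(risk_ratio(5, 50, 0, 50)$undefined)
})

test_that("category summary counts, percentages and reference handling", {
  rows <- do.call(rbind, lapply(1:20, function(i)
    make_case(sprintf("c%02d", i),
              behavior = if (i <= 8) "in_situ" else "invasive",
              histology_icdo3 = if (i <= 8) 8500L else 8500L,
              stage = if (i <= 8) "0" else "I",
              surgery_class = if (i %% 4 == 0) "mastectomy" else "bcs")))
  co <- new_cohort(rows)
  s <- summarize_mastectomy(co, "behavior", reference_level = "in_situ")
  expect_equal(sum(s$n), 20)
  expect_equal(s$rr[s$reference], 1)
  expect_equal(s$pct, s$n_mastectomy / s$n)
  expect_error(summarize_mastectomy(co, "not_a_var"), "schema covariate")
})

test_that("trend test matches the textbook statistic and a permutation oracle", {
  # hand table: three levels of 100 with 10/20/30 events, scores 1,2,3
  rows <- do.call(rbind, lapply(1:300, function(i) {
    lev <- c(0.5, 1.5, 2.5)[ceiling(i / 100)]
    ev <- (i - 1) %% 100 < c(10, 20, 30)[ceiling(i / 100)]
    make_case(sprintf("c%03d", i), tumor_size_cm = lev,
              surgery_class = if (ev) "mastectomy" else "bcs")
  }))
  co <- new_cohort(rows)
  tt <- trend_test(co, "size_group")
  chi2_hand <- oracle_trend_chi2(c(10, 20, 30), c(100, 100, 100), 1:3)
  expect_equal(tt$statistic, chi2_hand, tolerance = 1e-12)

  # permutation oracle for the p-value
  set.seed(99)
  y <- rep(rep(c(1, 0), 3), times = c(10, 90, 20, 80, 30, 70))
  g <- rep(1:3, each = 100)
  T_obs <- abs(sum(y * g) - mean(y) * sum(g))
  perm <- replicate(4000, {
    ys <- sample(y)
    abs(sum(ys * g) - mean(ys) * sum(g))
  })
  p_perm <- mean(perm >= T_obs - 1e-9)
  expect_lt(abs(tt$p_value - p_perm), 0.004)
})

test_that("trend test degenerates and reduces correctly", {
  # identical proportions: statistic near 0, p near 1
  rows <- do.call(rbind, lapply(1:200, function(i)
    make_case(sprintf("c%03d", i), tumor_size_cm = c(0.5, 1.5)[1 + i %% 2],
              surgery_class = if (i %% 4 < 2) "mastectomy" else "bcs")))
  co <- new_cohort(rows)
  tt <- trend_test(co, "size_group")
  expect_lt(tt$statistic, 1e-9)
  expect_gt(tt$p_value, 0.99)

  # with two levels the trend test is the standard Pearson chi-squared test
  rows2 <- do.call(rbind, lapply(1:200, function(i)
    make_case(sprintf("c%03d", i), tumor_size_cm = c(0.5, 1.5)[1 + (i > 120)],
              surgery_class = if (i %% c(3, 5)[1 + (i > 120)] == 0)
                "mastectomy" else "bcs")))
  co2 <- new_cohort(rows2)
  tt2 <- trend_test(co2, "size_group")
  tab <- table(cohort_cases(co2)$tumor_size_cm > 1,
               cohort_cases(co2)$surgery_class == "mastectomy")
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(tt2$statistic, unname(ch$statistic), tolerance = 1e-9)
})

test_that("synthetic cohorts show the size trend and monotone risk ratios", {
  co <- generate_cohort(synthetic_config(n_cases = 20000, seed = 37))
  tt <- trend_test(co, "size_group")
  expect_lt(tt$p_value, 1e-4)
  s <- summarize_mastectomy(co, "size_group")
  rr_sized <- s$rr[s$level %in% c("0.0-0.9", "1.0-1.9", "2.0-2.9", "3.0-3.9",
                                  "4.0-4.9", "5.0+")]
  expect_true(all(diff(rr_sized) > 0))
  tt_age <- trend_test(co, "age_group")
  expect_lt(tt_age$p_value, 1e-4)
})
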