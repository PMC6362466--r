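test_that("generation is deterministic given the seed", {
  a <- generate_cohort(synthetic_config(n_cases = 1000, seed = 7))
  b <- generate_cohort(synthetic_config(n_cases = 1000, seed = 7))
  expect_identical(cohort_cases(a), cohort_cases(b))
  c <- generate_cohort(synthetic_config(n_cases = 1000, seed = 8))
  expect_false(identical(cohort_cases(a), cohort_cases(c)))
})

test_that("suppressing the overdiagnosis model yields zero flags", {
  om <- default_overdiagnosis_model()
  om$intercept <- -50
  co <- generate_cohort(synthetic_config(n_cases = 500, seed = 3,
                                         overdiagnosis_model = om))
  expect_false(any(cohort_cases(co)$overdiagnosed))
  expect_equal(true_overtreatment_rate(co), 0)
})

test_that("marginal mastectomy rate matches the calibrated 34% target", {
  co <- generate_cohort(synthetic_config(n_cases = 50000, seed = 42))
  obs <- mean(cohort_cases(co)$surgery_class == "mastectomy")
  se <- sqrt(0.34 * 0.66 / 50000)
  expect_lt(abs(obs - 0.34), 3 * se)
})

test_that("no generated overdiagnosis violates the rule-out criteria", {
  co <- generate_cohort(synthetic_config(n_cases = 20000, seed = 5))
  cases <- cohort_cases(co)
  expect_false(any(is_ruled_out(cases) & cases$overdiagnosed))
})

test_that("overdiagnosed and nonoverdiagnosed cases are exchangeable at delta = 0", {
  co <- generate_cohort(synthetic_config(n_cases = 40000, seed = 9))
  cases <- cohort_cases(co)
  m <- cases$surgery_class == "mastectomy"
  v <- cases$overdiagnosed
  # cases sharing a .true_p value share a covariate pattern for the mastectomy
  # model; within each, mastectomy rates among V and not-V must agree
  strata <- split(seq_len(nrow(cases)), cases$.true_p)
  checked <- 0
  for (idx in strata) {
    nv <- sum(v[idx]); nn <- sum(!v[idx])
    if (nv < 40 || nn < 40) next
    p1 <- mean(m[idx][v[idx]]); p0 <- mean(m[idx][!v[idx]])
    pool <- mean(m[idx])
    se <- sqrt(pool * (1 - pool) * (1 / nv + 1 / nn))
    expect_lt(abs(p1 - p0), 4 * se)
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})

test_that("a nonzero exchangeability violation shifts mastectomy toward overdiagnoses", {
  co <- generate_cohort(synthetic_config(n_cases = 40000, seed = 9,
                                         exchangeability_violation_delta = 1.5))
  cases <- cohort_cases(co)
  m <- cases$surgery_class == "mastectomy"
  v <- cases$overdiagnosed
  expect_gt(mean(m[v]), mean(m[!v]) - 0.02)  # delta pushes V cases upward
  # and the stored true_p marginalizes over the latent label
  cfg <- synthetic_config(n_cases = 40000, seed = 9,
                          exchangeability_violation_delta = 1.5)
  tp <- true_propensities(co, cfg)
  expect_equal(tp$p_hat, cases$.true_p, tolerance = 1e-6)
})

test_that("true overtreatment rate is the M-and-V count over n", {
  rows <- do.call(rbind, lapply(1:10, function(i)
    make_case(sprintf("c%02d", i),
              surgery_class = if (i <= 4) "mastectomy" else "bcs")))
  rows$overdiagnosed <- c(TRUE, TRUE, FALSE, FALSE, TRUE, rep(FALSE, 5))
  expect_equal(true_overtreatment_rate(new_cohort(rows)), 0.2)

  rows$surgery_class <- "mastectomy"
  rows$overdiagnosed <- TRUE
  expect_equal(true_overtreatment_rate(new_cohort(rows)), 1)

  expect_error(true_overtreatment_rate(make_cohort(make_case())),
               "overdiagnosed")
})

test_that("ground-truth propensities are the generating model's probabilities", {
  cfg <- synthetic_config(n_cases = 2000, seed = 21)
  co <- generate_cohort(cfg)
  tp <- true_propensities(co, cfg)
  expect_equal(tp$p_hat, cohort_cases(co)$.true_p, tolerance = 1e-6)
  expect_true(all(tp$tag == "oracle"))
})

test_that("YAML scenario presets reproduce configured generation", {
  def <- synthetic_config_from_yaml(
    system.file("extdata", "scenario_default.yaml", package = "overtreat"))
  expect_equal(def$n_cases, 5000L)
  expect_equal(def$delta, 0)
  expect_identical(cohort_cases(generate_cohort(def)),
                   cohort_cases(generate_cohort(synthetic_config())))
  viol <- synthetic_config_from_yaml(
    system.file("extdata", "scenario_violation.yaml", package = "overtreat"))
  expect_equal(viol$delta, 1.0)
  # model overrides round-trip through YAML
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_cases = 100, seed = 2,
                        mastectomy_model = list(intercept = -2)), path)
  cfg <- synthetic_config_from_yaml(path)
  expect_equal(cfg$mastectomy_model$intercept, -2)
  expect_equal(cfg$mastectomy_model$coef, default_mastectomy_model()$coef)
})
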