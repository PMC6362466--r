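test_that("lambda = 1 reduces exactly to the main analysis", {
  set.seed(3)
  p <- runif(30)
  for (q in c(0, 0.1, 0.25)) {
    a <- bound_overtreatment(p, 40, q)
    b <- sensitive_bounds(p, 40, q, lambda = 1)
    expect_equal(b$lower, a$lower)
    expect_equal(b$upper, a$upper)
  }
  expect_error(sensitive_bounds(p, 40, 0.1, lambda = 0.5), "lambda")
})

test_that("two-case closed form: mean-preserving odds shift", {
  b <- sensitive_bounds(c(0.5, 0.5), 2, 0.5, lambda = 3)
  # adversary moves one case to odds 3 (p = 0.75), the other to 0.25
  expect_equal(b$upper, 0.75 / 2)
  expect_equal(b$lower, 0.25 / 2)
})

test_that("lambda -> infinity approaches the mass-transport limit", {
  set.seed(5)
  p <- runif(12)
  n_total <- 12
  q <- 0.5  # q_eligible = 0.5, m = 6
  b <- sensitive_bounds(p, n_total, q, lambda = 1e6)
  expect_equal(b$upper, min(q * n_total, sum(p)) / n_total, tolerance = 1e-3)
  expect_equal(b$lower, max(0, sum(p) - (1 - q) * n_total) / n_total,
               tolerance = 1e-3)
})

test_that("water-filling bounds equal the exhaustive LP oracle on small instances", {
  set.seed(77)
  for (rep in 1:20) {
    n_elig <- sample(3:8, 1)
    n_total <- n_elig + sample(0:3, 1)
    p <- round(runif(n_elig, 0.05, 0.95), 3)
    m <- sample(1:(n_elig - 1), 1) - sample(c(0, 0.5), 1)
    q <- m / n_total
    lam <- sample(c(1.5, 3, 10), 1)
    got <- sensitive_bounds(p, n_total, q, lam)
    want <- oracle_sensitive(p, n_total, q, lam)
    expect_equal(got$lower, want$lower, tolerance = 1e-9)
    expect_equal(got$upper, want$upper, tolerance = 1e-9)
  }
})

test_that("intervals are nested and monotone in lambda and capped by q", {
  set.seed(11)
  p <- runif(50)
  q <- 0.3 * 50 / 60
  prev <- sensitive_bounds(p, 60, q, 1)
  for (lam in c(2, 5, 25, 100)) {
    cur <- sensitive_bounds(p, 60, q, lam)
    expect_lte(cur$lower, prev$lower + 1e-12)
    expect_gte(cur$upper, prev$upper - 1e-12)
    expect_gte(cur$lower, 0)
    expect_lte(cur$upper, q + 1e-12)
    prev <- cur
  }
})

test_that("sweep returns the main curve at lambda 1 and nested widening beyond", {
  cfg <- synthetic_config(n_cases = 3000, seed = 29)
  co <- generate_cohort(cfg)
  part <- apply_ruleout(co)
  p <- eligible_propensities(true_propensities(co, cfg), part$eligible)
  n_total <- n_cases(co)
  q_grid <- c(0.05, 0.15, 0.25)
  sw <- sensitivity_sweep(p, n_total, q_grid, c(1, 5, 25))
  main <- bounds_curve(p, n_total, q_grid)
  expect_equal(sw$lower[sw$lambda == 1], main$lower)
  expect_equal(sw$upper[sw$lambda == 1], main$upper)
  for (q in q_grid) {
    u <- sw$upper[sw$q == q]
    l <- sw$lower[sw$q == q]
    expect_true(all(diff(u) >= -1e-12))
    expect_true(all(diff(l) <= 1e-12))
    # widening saturates: over equal multiplicative OR steps (1 -> 5 -> 25)
    # the upper-bound inflation diminishes, approaching the mass-transport cap
    expect_gte(u[2] - u[1], u[3] - u[2] - 1e-9)
  }
})

test_that("an interval robust to the omitted covariate's OR covers the truth", {
  # generate with the full model, fit with her2 removed from the schema; the
  # her2 log-odds range is 0.4, conditional OR exp(0.4) = 1.49 <= lambda = 2
  reps <- 60
  covered <- 0
  for (r in seq_len(reps)) {
    cfg <- synthetic_config(n_cases = 2000, seed = 1000 + r)
    co <- generate_cohort(cfg)
    schema_red <- default_covariate_schema()
    schema_red$her2 <- NULL
    class(schema_red) <- "covariate_schema"
    co_red <- new_cohort(cohort_cases(co), schema_red)
    est <- fit_propensity(co_red, model_spec("logistic", seed = 1000 + r))
    part <- apply_ruleout(co_red)
    p <- eligible_propensities(est, part$eligible)
    q_real <- mean(cohort_cases(co)$overdiagnosed)
    b <- sensitive_bounds(p, n_cases(co), q_real, lambda = 2,
                          case_ids = cohort_cases(part$eligible)$case_id)
    truth <- true_overtreatment_rate(co)
    if (truth >= b$lower - 1e-12 && truth <= b$upper + 1e-12)
      covered <- covered + 1
  }
  expect_gte(covered / reps, 0.95)
})
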