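test_that("individual criteria trigger as specified and NA never excludes", {
  expect_true(is_ruled_out(make_case(nodes_positive = 2)))
  expect_true(is_ruled_out(make_case(nodes_positive = 5)))
  expect_false(is_ruled_out(make_case(nodes_positive = 1, tumor_size_cm = 3.9)))
  expect_true(is_ruled_out(make_case(tumor_size_cm = 4.0)))
  expect_false(is_ruled_out(make_case(tumor_size_cm = NA_real_,
                                      nodes_positive = NA_integer_)))
  expect_true(is_ruled_out(make_case(mets = TRUE)))
  expect_true(is_ruled_out(make_case(fascia = TRUE)))
  expect_true(is_ruled_out(make_case(skin = TRUE)))
  # NA flags do not trigger
  flagged <- make_case()
  flagged$distant_metastasis <- NA
  expect_false(is_ruled_out(flagged))
  # disabled criteria do not trigger
  crit <- ruleout_criteria(use_distant_metastasis = FALSE)
  expect_false(is_ruled_out(make_case(mets = TRUE), crit))
})

test_that("apply_ruleout partitions the cohort and tallies triggers", {
  co <- make_cohort(make_case(), make_case(tumor_size_cm = 0.8),
                    make_case(nodes_positive = 1),
                    make_case(stage = "IV", mets = TRUE))
  part <- apply_ruleout(co)
  expect_equal(n_cases(part$eligible), 3)
  expect_equal(n_cases(part$excluded), 1)
  expect_equal(part$report$n_eligible + part$report$n_excluded,
               part$report$n_input)
  expect_setequal(c(cohort_cases(part$eligible)$case_id,
                    cohort_cases(part$excluded)$case_id),
                  cohort_cases(co)$case_id)
  expect_equal(unname(part$report$triggers["metastasis"]), 1)

  benign <- make_cohort(make_case(), make_case(tumor_size_cm = 1.0))
  expect_equal(n_cases(apply_ruleout(benign)$excluded), 0)
})

test_that("tightening any threshold can only shrink the eligible set", {
  co <- generate_cohort(synthetic_config(n_cases = 3000, seed = 13))
  loose <- apply_ruleout(co, ruleout_criteria())
  strict <- apply_ruleout(co, ruleout_criteria(min_nodes_ruleout = 1,
                                               min_size_cm_ruleout = 3.0))
  expect_lte(n_cases(strict$eligible), n_cases(loose$eligible))
  expect_true(all(cohort_cases(strict$eligible)$case_id %in%
                  cohort_cases(loose$eligible)$case_id))
})

test_that("DCIS mode keeps only in situ cases with DCIS histology codes", {
  co <- generate_cohort(synthetic_config(n_cases = 3000, seed = 17))
  part <- apply_ruleout(co, dcis_criteria())
  kept <- cohort_cases(part$eligible)
  expect_true(all(kept$behavior == "in_situ"))
  expect_true(all(kept$histology_icdo3 %in% dcis_histology_codes()))
  expect_gt(nrow(kept), 0)
  # invasive 8500 is excluded even though the code matches
  inv <- make_case(histology_icdo3 = 8500, behavior = "invasive")
  expect_true(is_ruled_out(inv, dcis_criteria()))
})

test_that("criteria serialize to YAML and back", {
  crit <- ruleout_criteria(min_nodes_ruleout = 1, min_size_cm_ruleout = 3.0,
                           use_skin_ulceration = FALSE)
  path <- tempfile(fileext = ".yaml")
  criteria_to_yaml(crit, path)
  expect_equal(criteria_from_yaml(path), crit)
  dc <- dcis_criteria()
  criteria_to_yaml(dc, path)
  expect_equal(criteria_from_yaml(path), dc)
})

test_that("alternative criteria sweep: stricter sets shrink the eligible pool, lower bounds move less than upper", {
  cfg <- synthetic_config(n_cases = 4000, seed = 23)
  co <- generate_cohort(cfg)
  est <- true_propensities(co, cfg)
  sets <- list(default = ruleout_criteria(),
               strict = ruleout_criteria(min_nodes_ruleout = 1,
                                         min_size_cm_ruleout = 3.0))
  q_grid <- c(0.1, 0.2)
  sw <- alternative_criteria_sweep(co, est, sets, q_grid)
  expect_equal(nrow(sw), 4)
  n_def <- unique(sw$n_eligible[sw$criteria == "default"])
  n_str <- unique(sw$n_eligible[sw$criteria == "strict"])
  expect_lt(n_str, n_def)
  # identical criteria give identical curves
  sw2 <- alternative_criteria_sweep(co, est, list(a = sets$default,
                                                  b = ruleout_criteria()), q_grid)
  expect_equal(sw2$lower[sw2$criteria == "a"], sw2$lower[sw2$criteria == "b"])
  expect_equal(sw2$upper[sw2$criteria == "a"], sw2$upper[sw2$criteria == "b"])
  # lower bounds are less sensitive to the criteria choice than upper bounds
  for (q in q_grid) {
    dl <- abs(diff(sw$lower[sw$q == q]))
    du <- abs(diff(sw$upper[sw$q == q]))
    expect_lte(dl, du + 1e-12)
  }
})
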