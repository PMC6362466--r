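# End-to-end orchestration: simulate or read a cohort, summarize it, apply the
# rule-out criteria, estimate propensities on the full cohort, compute the
# bounds curve on the eligible subset, and run the omitted-variable
# sensitivity sweep. All stage outputs are written to the output directory and
# a machine-readable JSON report is assembled. Fully deterministic given the
# config seed (timings are logged to stderr, never written to artifacts).

#' Pipeline run configuration
#'
#' @param input a cohort CSV path, a `synthetic_config`, or `NULL` to use the
#'   default synthetic scenario.
#' @param criteria rule-out criteria; the DCIS restriction is added when
#'   `dcis_mode = TRUE`.
#' @param spec propensity [model_spec()]; its seed is overridden by `seed`.
#' @param q_grid overdiagnosed fractions of the full cohort for the bounds
#'   curve; defaults to `seq(0, q_max, by = 0.01)`.
#' @param q_max ceiling of the default q grid, e.g. from
#'   [q_max_from_incidence()].
#' @param headline_q q values at which outward-rounded headline intervals are
#'   reported; defaults to `c(0.1, 0.2, 0.3, q_max)` clipped to feasibility.
#' @param lambda_list odds ratios for the sensitivity sweep.
#' @param output_dir directory for stage artifacts; created if missing.
#' @param seed master seed for simulation and model fitting.
#' @param dcis_mode if TRUE, restrict the eligible set to DCIS histologies
#'   before bounding.
#' @param schema covariate schema used when reading a CSV cohort.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, criteria = ruleout_criteria(),
                       spec = model_spec(), q_grid = NULL, q_max = 0.37,
                       headline_q = NULL, lambda_list = c(1, 5, 25),
                       output_dir = tempfile("overtreat_run_"), seed = 1L,
                       dcis_mode = FALSE, schema = default_covariate_schema()) {
  stopifnot(q_max > 0, q_max <= 1, all(lambda_list >= 1))
  if (dcis_mode) {
    criteria$restrict_to_histologies <- dcis_histology_codes()
    criteria$restrict_to_behavior <- "in_situ"
  }
  structure(list(input = input, criteria = criteria, spec = spec,
                 q_grid = q_grid, q_max = q_max, headline_q = headline_q,
                 lambda_list = lambda_list, output_dir = output_dir,
                 seed = as.integer(seed), dcis_mode = dcis_mode,
                 schema = schema),
            class = "run_config")
}

stage_log <- function(stage, t0) {
  message(sprintf("[overtreat] %-12s %.2fs", stage,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full estimation pipeline
#'
#' Stages: simulate/read -> describe -> rule out -> propensity -> bounds ->
#' sensitivity. Stage artifacts (CSVs and the JSON report) are written under
#' `config$output_dir` and are sufficient to re-run any later stage in
#' isolation.
#'
#' @param config a [run_config()].
#' @return the run report (also written as `report.json`), invisibly: input
#'   and exclusion counts, propensity diagnostics, the bounds curve, the
#'   sensitivity sweep, and outward-rounded headline intervals.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)

  t0 <- Sys.time()
  cohort <- if (is.null(config$input)) {
    generate_cohort(synthetic_config(seed = config$seed))
  } else if (inherits(config$input, "synthetic_config")) {
    cfg <- config$input
    cfg$seed <- config$seed
    generate_cohort(cfg)
  } else if (is.character(config$input)) {
    read_cohort(config$input, config$schema)
  } else stop("input must be NULL, a synthetic_config or a CSV path")
  write_cohort(cohort, out("cohort.csv"))
  if ("overdiagnosed" %in% names(cohort_cases(cohort))) {
    gt <- cohort_cases(cohort)[, c("case_id", "overdiagnosed", ".true_p")]
    names(gt) <- c("case_id", "overdiagnosed", "true_p")
    utils::write.csv(gt, out("ground_truth.csv"), row.names = FALSE)
  }
  stage_log("input", t0)

  t0 <- Sys.time()
  desc_vars <- intersect(c("stage", "size_group", "nodes_group", "grade",
                           "age_group", "race"), names(cohort_schema(cohort)))
  descriptives <- lapply(stats::setNames(desc_vars, desc_vars), function(v)
    summarize_mastectomy(cohort, v))
  utils::write.csv(do.call(rbind, lapply(desc_vars, function(v)
    cbind(variable = v, as.data.frame(descriptives[[v]])))),
    out("descriptive.csv"), row.names = FALSE)
  stage_log("describe", t0)

  t0 <- Sys.time()
  part <- apply_ruleout(cohort, config$criteria)
  write_cohort(part$eligible, out("eligible.csv"))
  write_cohort(part$excluded, out("excluded.csv"))
  stage_log("ruleout", t0)

  t0 <- Sys.time()
  spec <- config$spec
  spec$seed <- config$seed
  estimates <- fit_propensity(cohort, spec)
  utils::write.csv(as.data.frame(estimates), out("propensity.csv"),
                   row.names = FALSE)
  diagnostics <- propensity_diagnostics(estimates, cohort)
  stage_log("propensity", t0)

  t0 <- Sys.time()
  n_total <- n_cases(cohort)
  p_elig <- eligible_propensities(estimates, part$eligible)
  elig_ids <- cohort_cases(part$eligible)$case_id
  q_feas <- length(p_elig) / n_total
  q_max <- min(config$q_max, q_feas)
  q_grid <- if (is.null(config$q_grid)) seq(0, q_max, by = 0.01) else config$q_grid
  curve <- bounds_curve(p_elig, n_total, q_grid, case_ids = elig_ids)
  utils::write.csv(as.data.frame(curve), out("bounds_curve.csv"),
                   row.names = FALSE)
  headline_q <- config$headline_q
  if (is.null(headline_q)) headline_q <- unique(pmin(c(0.1, 0.2, 0.3, q_max), q_max))
  headline <- lapply(headline_q, function(q) {
    b <- bound_overtreatment(p_elig, n_total, q, case_ids = elig_ids)
    r <- round_outward(100 * b$lower, 100 * b$upper)
    list(q = q, lower = b$lower, upper = b$upper,
         lower_pct_rounded = unname(r["lower"]),
         upper_pct_rounded = unname(r["upper"]))
  })
  stage_log("bounds", t0)

  t0 <- Sys.time()
  sweep <- sensitivity_sweep(p_elig, n_total, q_grid, config$lambda_list,
                             case_ids = elig_ids)
  utils::write.csv(as.data.frame(sweep), out("sensitivity.csv"),
                   row.names = FALSE)
  stage_log("sensitivity", t0)

  report <- list(
    seed = config$seed,
    dcis_mode = config$dcis_mode,
    n_total = n_total,
    exclusion_report = exclusion_report(cohort),
    ruleout = part$report,
    propensity = list(
      family = spec$model_family, n_trees = spec$n_trees,
      brier = diagnostics$brier, c_statistic = diagnostics$c_statistic),
    q_max = q_max,
    headline = headline,
    bounds_curve = as.data.frame(curve),
    sensitivity = as.data.frame(sweep)
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
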