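# Rule-out criteria (Information A): case characteristics so aggressive,
# advanced, or imminently clinically evident that overdiagnosis is excluded.
# Unknown (NA) values never trigger a criterion: misclassifying an
# overdiagnosis as a nonoverdiagnosis would invalidate the bounds, so the
# conservative direction is to keep cases with missing measurements eligible.

#' ICD-O-3 histology codes defining DCIS
#' @export
dcis_histology_codes <- function() c(8201L, 8230L, 8500:8507, 8523L)

#' Rule-out criteria
#'
#' Default thresholds: 2 or more invaded lymph nodes; tumour diameter 4.0 cm or
#' more; invasion to the pectoral fascia, muscle or chest wall; invasion to the
#' skin of the breast with ulceration or to adjacent skin; distant metastasis.
#' `restrict_to_histologies` switches to the DCIS-style mode in which every
#' case *not* matching the given histology codes (and, if set,
#' `restrict_to_behavior`) is ruled out.
#'
#' @param min_nodes_ruleout integer; rule out at this many positive nodes or
#'   more.
#' @param min_size_cm_ruleout tumour diameter (cm) at or above which a case is
#'   ruled out.
#' @param use_fascia_invasion,use_skin_ulceration,use_distant_metastasis enable
#'   the corresponding boolean criteria.
#' @param restrict_to_histologies optional integer vector of ICD-O-3 codes;
#'   cases with other codes are ruled out.
#' @param restrict_to_behavior optional behaviour (`"in_situ"`/`"invasive"`)
#'   required when `restrict_to_histologies` is set.
#' @return object of class `ruleout_criteria`.
#' @export
ruleout_criteria <- function(min_nodes_ruleout = 2L,
                             min_size_cm_ruleout = 4.0,
                             use_fascia_invasion = TRUE,
                             use_skin_ulceration = TRUE,
                             use_distant_metastasis = TRUE,
                             restrict_to_histologies = NULL,
                             restrict_to_behavior = NULL) {
  stopifnot(min_nodes_ruleout > 0, min_size_cm_ruleout > 0)
  structure(list(min_nodes_ruleout = as.integer(min_nodes_ruleout),
                 min_size_cm_ruleout = as.numeric(min_size_cm_ruleout),
                 use_fascia_invasion = isTRUE(use_fascia_invasion),
                 use_skin_ulceration = isTRUE(use_skin_ulceration),
                 use_distant_metastasis = isTRUE(use_distant_metastasis),
                 restrict_to_histologies =
                   if (!is.null(restrict_to_histologies))
                     as.integer(restrict_to_histologies),
                 restrict_to_behavior = restrict_to_behavior),
            class = "ruleout_criteria")
}

#' @rdname ruleout_criteria
#' @export
dcis_criteria <- function() {
  ruleout_criteria(restrict_to_histologies = dcis_histology_codes(),
                   restrict_to_behavior = "in_situ")
}

#' @export
print.ruleout_criteria <- function(x, ...) {
  cat("Rule-out criteria (any triggers exclusion):\n")
  cat("  >=", x$min_nodes_ruleout, "positive lymph nodes\n")
  cat("  >=", x$min_size_cm_ruleout, "cm tumour diameter\n")
  if (x$use_fascia_invasion) cat("  invasion to fascia/muscle/chest wall\n")
  if (x$use_skin_ulceration) cat("  skin invasion with ulceration / adjacent skin\n")
  if (x$use_distant_metastasis) cat("  distant metastasis\n")
  if (!is.null(x$restrict_to_histologies))
    cat("  histology not in {", paste(x$restrict_to_histologies, collapse = ","),
        "}", if (!is.null(x$restrict_to_behavior))
          paste0(" or behavior != ", x$restrict_to_behavior), "\n", sep = "")
  invisible(x)
}

# Per-criterion trigger matrix (rows = cases, cols = criteria); NA in a
# measurement contributes FALSE for that criterion.
ruleout_triggers <- function(cases, criteria) {
  n <- nrow(cases)
  tf <- function(x) !is.na(x) & x
  trig <- cbind(
    nodes      = tf(cases$nodes_positive >= criteria$min_nodes_ruleout),
    size       = tf(cases$tumor_size_cm >= criteria$min_size_cm_ruleout),
    fascia     = if (criteria$use_fascia_invasion)
                   tf(cases$invades_fascia_muscle_chestwall) else rep(FALSE, n),
    skin       = if (criteria$use_skin_ulceration)
                   tf(cases$skin_ulceration_or_adjacent_skin) else rep(FALSE, n),
    metastasis = if (criteria$use_distant_metastasis)
                   tf(cases$distant_metastasis) else rep(FALSE, n)
  )
  if (!is.null(criteria$restrict_to_histologies)) {
    non_target <- !(cases$histology_icdo3 %in% criteria$restrict_to_histologies)
    if (!is.null(criteria$restrict_to_behavior))
      non_target <- non_target | cases$behavior != criteria$restrict_to_behavior
    trig <- cbind(trig, histology = non_target)
  }
  trig
}

#' Is a case ruled out from being overdiagnosed?
#'
#' @param cases a `cohort` or a case data.frame.
#' @param criteria a `ruleout_criteria`.
#' @return logical vector: TRUE if any enabled criterion is met. NA on a
#'   measurement never triggers its criterion.
#' @export
is_ruled_out <- function(cases, criteria = ruleout_criteria()) {
  if (inherits(cases, "cohort")) cases <- cohort_cases(cases)
  rowSums(ruleout_triggers(cases, criteria)) > 0
}

#' Partition a cohort by the rule-out criteria
#'
#' @param cohort a `cohort`.
#' @param criteria a `ruleout_criteria`.
#' @return list with elements `eligible` and `excluded` (both `cohort`s; their
#'   union is the input) and `report`: counts plus per-criterion trigger
#'   tallies (a case can trigger several criteria).
#' @export
apply_ruleout <- function(cohort, criteria = ruleout_criteria()) {
  cases <- cohort_cases(cohort)
  trig <- ruleout_triggers(cases, criteria)
  out <- rowSums(trig) > 0
  list(
    eligible = subset_cohort(cohort, !out),
    excluded = subset_cohort(cohort, out),
    report = list(
      n_input = nrow(cases),
      n_eligible = sum(!out),
      n_excluded = sum(out),
      eligible_fraction = if (nrow(cases)) mean(!out) else NA_real_,
      triggers = colSums(trig)
    )
  )
}

#' Bounds curves under alternative rule-out criteria
#'
#' Recomputes the eligible set and the fill-up bounds curve for each criteria
#' set, holding the propensity estimates fixed. Used to check how sensitive the
#' bounds are to the choice of rule-out thresholds.
#'
#' @param cohort the full study `cohort`.
#' @param estimates `propensity_estimates` for the full cohort.
#' @param criteria_list list of `ruleout_criteria`.
#' @param q_grid overdiagnosis proportions (of the full cohort) to evaluate.
#' @return data.frame with columns `criteria` (list index or name), `q`,
#'   `lower`, `upper`, `n_eligible`.
#' @export
alternative_criteria_sweep <- function(cohort, estimates, criteria_list, q_grid) {
  stopifnot(length(criteria_list) >= 1)
  nms <- names(criteria_list)
  if (is.null(nms)) nms <- as.character(seq_along(criteria_list))
  n_total <- n_cases(cohort)
  res <- lapply(seq_along(criteria_list), function(i) {
    part <- apply_ruleout(cohort, criteria_list[[i]])
    p <- eligible_propensities(estimates, part$eligible)
    curve <- bounds_curve(p, n_total, q_grid)
    data.frame(criteria = nms[i], q = curve$q, lower = curve$lower,
               upper = curve$upper, n_eligible = n_cases(part$eligible),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# ---- YAML (de)serialization -------------------------------------------------

#' Serialize rule-out criteria to/from YAML
#' @param criteria a `ruleout_criteria`.
#' @param path file path.
#' @return `criteria_to_yaml` returns `path` invisibly; `criteria_from_yaml`
#'   returns a `ruleout_criteria`.
#' @export
criteria_to_yaml <- function(criteria, path) {
  yaml::write_yaml(unclass(criteria)[!vapply(criteria, is.null, logical(1))], path)
  invisible(path)
}

#' @rdname criteria_to_yaml
#' @export
criteria_from_yaml <- function(path) {
  do.call(ruleout_criteria, yaml::read_yaml(path))
}
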