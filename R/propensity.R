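# Propensity of mastectomy, Pr(M | X) (Information C). Every case must be
# predicted by a model that did not train on it: out-of-bag predictions for
# the bagged random forest, K-fold cross-fitting for the logistic family. The
# oracle family reads the generating model's true probabilities from a
# synthetic cohort and exists for validation.

#' Propensity model specification
#'
#' Defaults follow common registry practice for a bagged classifier: 2500
#' trees, square-root-of-p variables tried per split, Gini splitting, leaf
#' size 1, hyperparameters not tuned. `n_random_splits` (a cap on candidate
#' splits for multivalue variables in some forest implementations) is recorded
#' for provenance but is advisory: the ranger backend's Gini splitting has no
#' equivalent control.
#'
#' @param model_family `"random_forest"`, `"logistic"` or `"oracle"`.
#' @param n_trees number of trees (random forest).
#' @param mtry variables tried per split; `NULL` means `floor(sqrt(p))`.
#' @param min_node_size minimal terminal node size.
#' @param n_random_splits advisory cap on random splits for multivalue
#'   variables (not used by the ranger backend).
#' @param k_folds folds for cross-fitting (logistic family).
#' @param seed integer seed controlling all model randomness.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(model_family = c("random_forest", "logistic", "oracle"),
                       n_trees = 2500L, mtry = NULL, min_node_size = 1L,
                       n_random_splits = 25L, k_folds = 5L, seed = 1L) {
  model_family <- match.arg(model_family)
  stopifnot(n_trees >= 1, k_folds >= 2)
  structure(list(model_family = model_family, n_trees = as.integer(n_trees),
                 mtry = mtry, min_node_size = as.integer(min_node_size),
                 n_random_splits = as.integer(n_random_splits),
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit the propensity model and predict honestly for every case
#'
#' @param cohort a `cohort` with both mastectomy and non-mastectomy cases.
#' @param spec a [model_spec()].
#' @return object of class `propensity_estimates`: data.frame with columns
#'   `case_id`, `p_hat`, `tag` (`"oob"`, `"crossfit_fold_k"` or `"oracle"`),
#'   carrying the spec as an attribute. Deterministic given the spec seed.
#' @export
fit_propensity <- function(cohort, spec = model_spec()) {
  cases <- cohort_cases(cohort)
  y <- cases$surgery_class == "mastectomy"
  if (spec$model_family != "oracle" && length(unique(y)) < 2)
    stop("cohort has a single outcome class; propensity model cannot be fit")
  est <- switch(spec$model_family,
    random_forest = fit_forest_oob(cohort, y, spec),
    logistic      = fit_logistic_crossfit(cohort, y, spec),
    oracle        = {
      if (!".true_p" %in% names(cases))
        stop("oracle family requires a synthetic cohort carrying .true_p")
      data.frame(case_id = cases$case_id, p_hat = cases$.true_p,
                 tag = "oracle", stringsAsFactors = FALSE)
    })
  stopifnot(nrow(est) == nrow(cases), all(est$p_hat >= 0 & est$p_hat <= 1))
  structure(est, class = c("propensity_estimates", "data.frame"),
            spec = spec)
}

fit_forest_oob <- function(cohort, y, spec) {
  x <- covariate_frame(cohort)
  mtry <- if (is.null(spec$mtry)) max(1L, floor(sqrt(ncol(x)))) else spec$mtry
  fit <- ranger::ranger(
    y = factor(y, levels = c(FALSE, TRUE)), x = x,
    num.trees = spec$n_trees, mtry = mtry, min.node.size = spec$min_node_size,
    splitrule = "gini", probability = TRUE,
    respect.unordered.factors = "order",
    seed = spec$seed, num.threads = 1, verbose = FALSE)
  p <- fit$predictions[, "TRUE"]
  # a case can miss OOB status in tiny cohorts with few trees; fall back to 0.5
  p[is.nan(p)] <- 0.5
  data.frame(case_id = cohort_cases(cohort)$case_id, p_hat = as.numeric(p),
             tag = "oob", stringsAsFactors = FALSE)
}

# Logistic cross-fit on a one-hot design built over the *full* schema levels,
# so folds share a common column space; coefficients for levels absent from a
# training fold are zeroed (that level then contributes the fold intercept).
fit_logistic_crossfit <- function(cohort, y, spec) {
  x <- covariate_frame(cohort)
  xm <- stats::model.matrix(~ ., data = x)
  n <- nrow(xm)
  k <- min(spec$k_folds, n)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  fold <- sample(rep_len(seq_len(k), n))
  p <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    keep <- colSums(abs(xm[tr, , drop = FALSE])) > 0
    fit <- suppressWarnings(
      stats::glm.fit(xm[tr, keep, drop = FALSE], y[tr],
                     family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    lp <- as.numeric(xm[!tr, keep, drop = FALSE] %*% beta)
    p[!tr] <- stats::plogis(lp)
  }
  data.frame(case_id = cohort_cases(cohort)$case_id, p_hat = p,
             tag = paste0("crossfit_fold_", fold), stringsAsFactors = FALSE)
}

#' Align propensity estimates with a (sub)cohort
#'
#' @param estimates a `propensity_estimates` (typically for the full cohort).
#' @param cohort a `cohort` whose cases must all be covered by `estimates`.
#' @return numeric vector of `p_hat` in the cohort's case order.
#' @export
eligible_propensities <- function(estimates, cohort) {
  ids <- cohort_cases(cohort)$case_id
  idx <- match(ids, estimates$case_id)
  if (anyNA(idx))
    stop("estimates are missing ", sum(is.na(idx)), " case(s)")
  estimates$p_hat[idx]
}

# ---- calibration / discrimination diagnostics --------------------------------

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes; 0 is perfect, 0.25 matches a constant 0.5 prediction.
#'
#' @param p_hat predicted probabilities.
#' @param outcome logical or 0/1 outcomes of the same length.
#' @return the mean of `(p_hat - outcome)^2`.
#' @export
brier_score <- function(p_hat, outcome) {
  if (length(p_hat) != length(outcome)) stop("length mismatch")
  mean((p_hat - as.numeric(outcome))^2)
}

#' Concordance statistic (area under the ROC curve)
#'
#' Probability that a randomly chosen positive case is ranked above a randomly
#' chosen negative case, counting ties as one half (midrank / Wilcoxon form).
#'
#' @inheritParams brier_score
#' @return c-statistic in [0, 1].
#' @export
c_statistic <- function(p_hat, outcome) {
  if (length(p_hat) != length(outcome)) stop("length mismatch")
  y <- as.logical(outcome)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(p_hat)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration curve by predicted-probability quantile bins
#'
#' @inheritParams brier_score
#' @param n_bins number of quantile bins (>= 1); duplicate quantile breaks are
#'   merged, so fewer bins can be returned for highly tied predictions.
#' @return data.frame with per-bin `n`, `mean_p_hat`, `observed_rate`; the
#'   counts sum to the number of cases.
#' @export
calibration_curve <- function(p_hat, outcome, n_bins = 10) {
  if (length(p_hat) != length(outcome)) stop("length mismatch")
  stopifnot(n_bins >= 1)
  y <- as.numeric(outcome)
  br <- unique(stats::quantile(p_hat, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE))
  if (length(br) < 2) br <- c(br - 1e-9, br + 1e-9)
  bin <- cut(p_hat, breaks = br, include.lowest = TRUE)
  out <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    mean_p_hat = as.numeric(tapply(p_hat, bin, mean)),
    observed_rate = as.numeric(tapply(y, bin, mean)),
    stringsAsFactors = FALSE)
  out
}

#' Propensity diagnostics bundle
#'
#' @param estimates `propensity_estimates` for a cohort.
#' @param cohort the matching `cohort`.
#' @param n_bins calibration bins.
#' @return list with `brier`, `c_statistic` and the calibration data.frame.
#' @export
propensity_diagnostics <- function(estimates, cohort, n_bins = 10) {
  y <- cohort_cases(cohort)$surgery_class == "mastectomy"
  p <- eligible_propensities(estimates, cohort)
  list(brier = brier_score(p, y),
       c_statistic = c_statistic(p, y),
       calibration = calibration_curve(p, y, n_bins))
}
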