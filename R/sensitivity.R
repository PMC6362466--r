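# Omitted-variable sensitivity analysis. The estimated propensities are
# assumed unbiased on average but omitted variables or informative missingness
# could move individual cases' mastectomy probabilities by up to a factor
# Lambda on the odds scale. An adversary picks perturbed propensities p* with
# |logit p*_i - logit p_i| <= log(Lambda), preserving the propensity mean
# (calibration in the large), to widen the fill-up bound as much as possible.
#
# Because the per-case odds windows [lo_i, hi_i] are monotone transforms of
# p_i, the orderings of p, lo and hi coincide; the adversarial optimum is
# therefore attained by selecting the same extreme-propensity cases as the
# main analysis and water-filling the fixed total propensity mass into (upper
# bound) or out of (lower bound) the selected cases. Each inner problem is a
# box-constrained LP with one equality constraint, solved exactly by greedy
# allocation; tests verify against an exhaustive LP oracle on small instances.

# Solve optimize sum(coef * x) s.t. lo <= x <= hi, sum(x) = total.
# Greedy: start at lo and allocate the remaining mass to coordinates in order
# of decreasing (maximize) or increasing (minimize) coefficient.
knapsack_eq <- function(coef, lo, hi, total, maximize = TRUE) {
  stopifnot(length(coef) == length(lo), length(lo) == length(hi),
            all(lo <= hi + 1e-12))
  if (total < sum(lo) - 1e-9 || total > sum(hi) + 1e-9)
    stop("equality-constrained knapsack infeasible")
  x <- lo
  budget <- total - sum(lo)
  ord <- order(coef, decreasing = maximize)
  for (i in ord) {
    if (budget <= 1e-12) break
    add <- min(hi[i] - lo[i], budget)
    x[i] <- lo[i] + add
    budget <- budget - add
  }
  sum(coef * x)
}

# Per-case logit windows under odds-ratio Lambda; exact at p = 0 and p = 1.
logit_window <- function(p, lambda) {
  lg <- log(lambda)
  lp <- stats::qlogis(p)
  list(lo = stats::plogis(lp - lg), hi = stats::plogis(lp + lg))
}

#' Omitted-variable-robust bounds on the overtreatment proportion
#'
#' Widens [bound_overtreatment()] against omitted variables and informative
#' missingness: each case's propensity may be perturbed by at most `lambda` on
#' the odds scale, subject to the overall propensity mean being preserved
#' (the perturbation can sharpen discrimination but not shift calibration in
#' the large). `lambda = 1` reproduces the main analysis exactly; the interval
#' is non-decreasing (nested) in `lambda` and always within `[0, q_total]`.
#'
#' @inheritParams bound_overtreatment
#' @param lambda odds ratio >= 1 bounding the per-case perturbation.
#' @return a `bounds_interval` with an additional `lambda` element.
#' @export
sensitive_bounds <- function(p, n_total, q_total, lambda, case_ids = NULL) {
  if (lambda < 1) stop("lambda must be >= 1")
  base <- bound_overtreatment(p, n_total, q_total, case_ids)
  if (lambda == 1 || q_total == 0) {
    base$lambda <- lambda
    return(base)
  }
  n_elig <- length(p)
  m <- q_total * n_total
  win <- logit_window(p, lambda)
  S <- sum(p)
  ord <- if (is.null(case_ids)) order(p) else order(p, case_ids)
  k <- floor(m + 1e-9)
  frac <- m - k
  if (frac < 1e-9) frac <- 0

  # coefficient vector for a fill of the m extreme cases at one end of `ord`
  fill_coef <- function(idx_sorted) {
    coef <- numeric(n_elig)
    if (k > 0) coef[idx_sorted[seq_len(k)]] <- 1
    if (frac > 0 && k < n_elig) coef[idx_sorted[k + 1]] <- frac
    coef
  }
  up_coef <- fill_coef(rev(ord))   # largest propensities selected
  lo_coef <- fill_coef(ord)        # smallest propensities selected
  upper <- knapsack_eq(up_coef, win$lo, win$hi, S, maximize = TRUE) / n_total
  lower <- knapsack_eq(lo_coef, win$lo, win$hi, S, maximize = FALSE) / n_total
  structure(list(q_total = q_total, q_eligible = base$q_eligible,
                 lower = max(0, min(lower, base$lower)),
                 upper = min(q_total, max(upper, base$upper)),
                 n_total = n_total, n_eligible = n_elig, lambda = lambda),
            class = "bounds_interval")
}

#' Sensitivity sweep over odds ratios and overdiagnosis proportions
#'
#' @inheritParams sensitive_bounds
#' @param q_grid overdiagnosed fractions of the full cohort.
#' @param lambda_list odds ratios (each >= 1).
#' @return data.frame of class `sensitivity_sweep`: columns `lambda`, `q`,
#'   `lower`, `upper`. Curves are nested in `lambda`.
#' @export
sensitivity_sweep <- function(p, n_total, q_grid, lambda_list, case_ids = NULL) {
  rows <- lapply(lambda_list, function(lam) {
    do.call(rbind, lapply(q_grid, function(q) {
      b <- sensitive_bounds(p, n_total, q, lam, case_ids)
      data.frame(lambda = lam, q = q, lower = b$lower, upper = b$upper)
    }))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_sweep", "data.frame")
  out
}

#' Plot a family of sensitivity curves
#'
#' @param x a `sensitivity_sweep`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sensitivity_sweep <- function(x, ...) {
  lambdas <- sort(unique(x$lambda))
  graphics::plot(range(100 * x$q), range(100 * c(x$lower, x$upper)), type = "n",
                 xlab = "Study population overdiagnosed (%)",
                 ylab = "Mastectomy for overdiagnosed cancer (%)", ...)
  for (i in seq_along(lambdas)) {
    sub <- x[x$lambda == lambdas[i], ]
    graphics::lines(100 * sub$q, 100 * sub$lower, lty = i)
    graphics::lines(100 * sub$q, 100 * sub$upper, lty = i)
  }
  graphics::legend("topleft", legend = paste("OR =", lambdas),
                   lty = seq_along(lambdas), bty = "n")
  invisible(x)
}
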