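# The fill-up partial-identification bound. Under conditional exchangeability,
# Pr(M, V) = sum_i Pr(M | X = x_i) Pr(V | X = x_i) Pr(X = x_i) with only
# Pr(V | X) unknown. Constraining the overdiagnosed fraction of eligible cases
# to q_eligible leaves Pr(V | X = x_i) free in [0, 1] with a fixed mean; the
# extreme values of the sum assign overdiagnosis to the cases with the
# smallest (lower bound) or largest (upper bound) mastectomy propensities.

#' Rescale an overdiagnosis proportion to the eligible subset
#'
#' The assumed proportion `q_total` refers to the full study population; after
#' the rule-out step only `n_eligible` cases can be overdiagnosed, so the
#' proportion among them is `q_total * n_total / n_eligible` (e.g. 30% of the
#' cohort with 75% eligible means 40% of the eligible cases).
#'
#' @param q_total assumed overdiagnosed fraction of the full cohort, in [0, 1].
#' @param n_total number of cases in the full cohort.
#' @param n_eligible number of eligible (not ruled out) cases.
#' @return `q_eligible` in [0, 1].
#' @export
rescale_q <- function(q_total, n_total, n_eligible) {
  stopifnot(q_total >= 0, q_total <= 1, n_eligible <= n_total, n_eligible >= 0)
  if (q_total == 0) return(0)
  q_eligible <- q_total * n_total / n_eligible
  if (q_eligible > 1 + 1e-12)
    stop("assumed overdiagnosis proportion inconsistent with rule-out criteria: ",
         "q_total = ", q_total, " implies ", signif(q_eligible, 4),
         " of eligible cases overdiagnosed")
  min(q_eligible, 1)
}

# Fractional top/bottom-m sum of p: sum of the floor(m) extreme values plus
# frac(m) times the next. Assumes p already sorted in the wanted direction.
fractional_prefix_sum <- function(p_sorted, m) {
  if (m <= 0) return(0)
  k <- floor(m + 1e-9)
  frac <- m - k
  if (frac < 1e-9) frac <- 0
  s <- if (k > 0) sum(p_sorted[seq_len(min(k, length(p_sorted)))]) else 0
  if (frac > 0 && k < length(p_sorted)) s <- s + frac * p_sorted[k + 1]
  s
}

#' Fill-up bounds on the overtreatment proportion
#'
#' Lower and upper bounds on Pr(M, V), the fraction of the *full* study
#' population that underwent mastectomy for overdiagnosed cancer, given the
#' mastectomy propensities of the eligible cases and an assumed overdiagnosis
#' proportion. The overdiagnosed group (m = q_total * n_total cases, possibly
#' fractional) is filled with the eligible cases of smallest/largest
#' propensity; the marginal case receives fractional weight, which makes the
#' bound continuous in q and equal to the linear-programming relaxation over
#' per-case overdiagnosis probabilities in [0, 1].
#'
#' @param p numeric vector of eligible-case propensities in [0, 1].
#' @param n_total size of the full cohort (eligible + ruled out).
#' @param q_total assumed overdiagnosed fraction of the full cohort.
#' @param case_ids optional ids used to stabilize the sort order under ties
#'   (ties do not affect the bound values).
#' @return object of class `bounds_interval`: list with `q_total`,
#'   `q_eligible`, `lower`, `upper`, `n_total`, `n_eligible`.
#' @export
bound_overtreatment <- function(p, n_total, q_total, case_ids = NULL) {
  stopifnot(all(p >= 0 & p <= 1), n_total >= length(p))
  n_elig <- length(p)
  q_eligible <- rescale_q(q_total, n_total, n_elig)
  m <- q_total * n_total
  ord <- if (is.null(case_ids)) order(p) else order(p, case_ids)
  p_asc <- p[ord]
  lower <- fractional_prefix_sum(p_asc, m) / n_total
  upper <- fractional_prefix_sum(rev(p_asc), m) / n_total
  structure(list(q_total = q_total, q_eligible = q_eligible,
                 lower = max(0, lower), upper = min(upper, q_total),
                 n_total = n_total, n_eligible = n_elig),
            class = "bounds_interval")
}

#' @export
print.bounds_interval <- function(x, ...) {
  cat(sprintf(
    "Pr(M,V) bounds at q = %.3f (q_eligible = %.3f): [%.4f, %.4f] (%.1f%% - %.1f%%)\n",
    x$q_total, x$q_eligible, x$lower, x$upper, 100 * x$lower, 100 * x$upper))
  if (!is.null(x$lambda))
    cat("  omitted-variable sensitivity OR =", x$lambda, "\n")
  invisible(x)
}

#' Bounds curve over a grid of overdiagnosis proportions
#'
#' @inheritParams bound_overtreatment
#' @param q_grid numeric vector of overdiagnosed fractions of the full cohort;
#'   every value must be feasible under the eligible-case count.
#' @return data.frame of class `bounds_curve` with columns `q`, `q_eligible`,
#'   `lower`, `upper`, `lower_pct_rounded`, `upper_pct_rounded`.
#' @export
bounds_curve <- function(p, n_total, q_grid, case_ids = NULL) {
  rows <- lapply(q_grid, function(q) {
    b <- bound_overtreatment(p, n_total, q, case_ids)
    r <- round_outward(100 * b$lower, 100 * b$upper)
    data.frame(q = q, q_eligible = b$q_eligible, lower = b$lower,
               upper = b$upper, lower_pct_rounded = r[["lower"]],
               upper_pct_rounded = r[["upper"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bounds_curve", "data.frame")
  attr(out, "n_total") <- n_total
  attr(out, "n_eligible") <- length(p)
  out
}

#' Ceiling on the overdiagnosis proportion from incidence trends
#'
#' If nonoverdiagnosed incidence has been constant or increasing and screening
#' accounts for essentially all overdiagnosis, the overdiagnosed share of
#' current cases can be at most the relative incidence increase since the
#' pre-screening era: `1 - rate_early / rate_late`.
#'
#' @param rate_early age-standardized incidence per 100,000 in the
#'   pre-screening reference year.
#' @param rate_late age-standardized incidence per 100,000 in the study year.
#' @return maximal overdiagnosed fraction, in [0, 1).
#' @export
q_max_from_incidence <- function(rate_early, rate_late) {
  stopifnot(rate_early > 0, rate_late > 0)
  if (rate_late < rate_early)
    stop("incidence decreased: overdiagnosis ceiling would be negative")
  1 - rate_early / rate_late
}

#' Age-standardized rate
#'
#' Weighted mean of age-specific rates using a standard population's weights.
#'
#' @param rates age-stratum-specific rates.
#' @param weights standard-population weights (non-negative, positive sum).
#' @return the standardized rate.
#' @export
age_standardize <- function(rates, weights) {
  stopifnot(length(rates) == length(weights))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must have positive sum")
  sum(rates * weights) / sum(weights)
}

#' Outward rounding of a percentage interval
#'
#' Conservative presentation of a bound: the lower endpoint is floored and the
#' upper endpoint is ceiled to whole percents, so the reported interval always
#' contains the computed one (5.6-12.4 becomes 5-13).
#'
#' @param lower_pct,upper_pct interval endpoints in percent, `lower <= upper`.
#' @return named numeric vector `c(lower=, upper=)` of integer percents.
#' @export
round_outward <- function(lower_pct, upper_pct) {
  stopifnot(all(lower_pct <= upper_pct + 1e-12))
  c(lower = floor(lower_pct), upper = ceiling(upper_pct))
}

#' Plot a bounds curve
#'
#' @param x a `bounds_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bounds_curve <- function(x, ...) {
  graphics::plot(100 * x$q, 100 * x$upper, type = "n",
                 xlab = "Study population overdiagnosed (%)",
                 ylab = "Mastectomy for overdiagnosed cancer (%)", ...)
  graphics::polygon(c(100 * x$q, rev(100 * x$q)),
                    c(100 * x$lower, rev(100 * x$upper)),
                    col = "grey80", border = NA)
  graphics::lines(100 * x$q, 100 * x$lower)
  graphics::lines(100 * x$q, 100 * x$upper)
  invisible(x)
}
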