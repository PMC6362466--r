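# Independent brute-force oracles. These enumerate, rather than sort or
# water-fill, so they share no code path with the implementation.

# Fill-up bound by exhaustive enumeration: min/max over all assignments of
# overdiagnosis weight m across eligible cases, where m = q_total * n_total.
# Integer m: all size-m subsets. Fractional m: all (subset of size floor(m),
# extra case with weight frac) combinations.
oracle_fillup <- function(p, n_total, q_total) {
  n <- length(p)
  m <- q_total * n_total
  k <- floor(m + 1e-9)
  frac <- m - k
  if (frac < 1e-9) frac <- 0
  if (m == 0) return(list(lower = 0, upper = 0))
  vals <- c()
  subsets <- if (k == 0) list(integer(0)) else
    asplit(utils::combn(n, k), 2)
  for (A in subsets) {
    base <- sum(p[A])
    if (frac == 0) {
      vals <- c(vals, base)
    } else {
      for (kk in setdiff(seq_len(n), A))
        vals <- c(vals, base + frac * p[kk])
    }
  }
  list(lower = min(vals) / n_total, upper = max(vals) / n_total)
}

# Closed-form optimum of: optimize sum(coef * x) over lo <= x <= hi,
# sum(x) = total (a box LP with one equality constraint). Written here from
# first principles for the oracle.
oracle_box_lp <- function(coef, lo, hi, total, maximize) {
  x <- lo
  remaining <- total - sum(lo)
  stopifnot(remaining >= -1e-9, remaining <= sum(hi - lo) + 1e-9)
  for (i in order(coef, decreasing = maximize)) {
    step <- min(hi[i] - lo[i], max(remaining, 0))
    x[i] <- lo[i] + step
    remaining <- remaining - step
  }
  sum(coef * x)
}

# Omitted-variable-robust fill-up bound by exhaustive enumeration over every
# possible selection of the overdiagnosed group, solving the adversary's
# propensity-perturbation LP exactly for each selection.
oracle_sensitive <- function(p, n_total, q_total, lambda) {
  n <- length(p)
  m <- q_total * n_total
  if (m == 0) return(list(lower = 0, upper = 0))
  k <- floor(m + 1e-9)
  frac <- m - k
  if (frac < 1e-9) frac <- 0
  lg <- log(lambda)
  lo <- plogis(qlogis(p) - lg)
  hi <- plogis(qlogis(p) + lg)
  S <- sum(p)
  uppers <- c(); lowers <- c()
  subsets <- if (k == 0) list(integer(0)) else asplit(utils::combn(n, k), 2)
  for (A in subsets) {
    coefs_list <- if (frac == 0) {
      cf <- numeric(n); cf[A] <- 1
      list(cf)
    } else {
      lapply(setdiff(seq_len(n), A), function(kk) {
        cf <- numeric(n); cf[A] <- 1; cf[kk] <- frac
        cf
      })
    }
    for (cf in coefs_list) {
      uppers <- c(uppers, oracle_box_lp(cf, lo, hi, S, TRUE))
      lowers <- c(lowers, oracle_box_lp(cf, lo, hi, S, FALSE))
    }
  }
  list(lower = min(lowers) / n_total, upper = max(uppers) / n_total)
}

# Textbook Cochran-Armitage chi-squared statistic for trend in proportions.
oracle_trend_chi2 <- function(events, totals, scores) {
  N <- sum(totals)
  pbar <- sum(events) / N
  T_obs <- sum(scores * events)
  E <- pbar * sum(totals * scores)
  V <- pbar * (1 - pbar) *
    (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  (T_obs - E)^2 / V
}
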