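# Registry-table descriptive summaries: per-category mastectomy counts and
# percentages, univariate risk ratios with log-Wald 95% CIs (unconditional
# maximum likelihood), and the Cochran-Armitage chi-squared test for trend.

#' Risk ratio with log-Wald 95% confidence interval
#'
#' RR = (a/n1) / (b/n0) with CI
#' `exp(log RR +/- 1.96 * sqrt(1/a - 1/n1 + 1/b - 1/n0))`, the unconditional
#' maximum-likelihood (Wald) interval conventional in registry tables.
#'
#' @param a events in the index group; `n1` its size.
#' @param b events in the reference group; `n0` its size.
#' @param n1,n0 group sizes.
#' @return list with `rr`, `ci_low`, `ci_high`, `undefined` (TRUE when a zero
#'   cell makes the interval undefined).
#' @export
risk_ratio <- function(a, n1, b, n0) {
  stopifnot(n1 > 0, n0 > 0, a >= 0, b >= 0, a <= n1, b <= n0)
  if (b == 0 || a == 0) {
    return(list(rr = if (b == 0) NA_real_ else 0, ci_low = NA_real_,
                ci_high = NA_real_, undefined = TRUE))
  }
  rr <- (a / n1) / (b / n0)
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n0)
  list(rr = rr, ci_low = rr * exp(-1.96 * se), ci_high = rr * exp(1.96 * se),
       undefined = FALSE)
}

# percent formatted to one decimal, half-up, for printed-table comparability
format_pct <- function(x) sprintf("%.1f", floor(1000 * x + 0.5) / 10)

#' Per-category mastectomy summary with univariate risk ratios
#'
#' One row per level of a schema covariate (including the `"NA"` level):
#' case count, mastectomy count and percentage, and the risk ratio versus the
#' reference level with its 95% CI.
#'
#' @param cohort a `cohort`.
#' @param variable name of a schema covariate (e.g. `"stage"`, `"size_group"`).
#' @param reference_level reference category; defaults to the first schema
#'   level.
#' @return data.frame of class `category_summary` with columns `level`, `n`,
#'   `n_mastectomy`, `pct`, `rr`, `ci_low`, `ci_high`, `reference`.
#' @export
summarize_mastectomy <- function(cohort, variable, reference_level = NULL) {
  schema <- cohort_schema(cohort)
  if (!variable %in% names(schema))
    stop("'", variable, "' is not a schema covariate")
  frame <- covariate_frame(cohort)
  x <- frame[[variable]]
  y <- cohort_cases(cohort)$surgery_class == "mastectomy"
  levels_present <- levels(x)[table(x) > 0]
  if (is.null(reference_level)) reference_level <- levels_present[1]
  if (!reference_level %in% levels_present)
    stop("reference level '", reference_level, "' has no cases")
  n0 <- sum(x == reference_level)
  b <- sum(y[x == reference_level])
  rows <- lapply(levels_present, function(lv) {
    n1 <- sum(x == lv)
    a <- sum(y[x == lv])
    if (lv == reference_level) {
      rr <- list(rr = 1, ci_low = NA_real_, ci_high = NA_real_, undefined = FALSE)
    } else {
      rr <- risk_ratio(a, n1, b, n0)
    }
    data.frame(level = lv, n = n1, n_mastectomy = a, pct = a / n1,
               rr = rr$rr, ci_low = rr$ci_low, ci_high = rr$ci_high,
               reference = lv == reference_level, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "variable") <- variable
  class(out) <- c("category_summary", "data.frame")
  out
}

#' @export
print.category_summary <- function(x, ...) {
  cat("Mastectomy by", attr(x, "variable"), "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-10s %6d  %5d (%s%%)  %s\n", x$level[i], x$n[i],
                x$n_mastectomy[i], format_pct(x$pct[i]),
                if (x$reference[i]) "Ref." else if (is.na(x$ci_low[i])) "-"
                else sprintf("%.1f (%.1f-%.1f)", x$rr[i], x$ci_low[i],
                             x$ci_high[i])))
  }
  invisible(x)
}

#' Chi-squared test for trend in mastectomy proportions
#'
#' Cochran-Armitage test across the ordered levels of a schema covariate,
#' with consecutive integer scores by default. The `"NA"` level is excluded
#' from the trend.
#'
#' @param cohort a `cohort`.
#' @param variable ordered schema covariate (e.g. `"size_group"`,
#'   `"age_group"`).
#' @param scores numeric scores for the ordered non-NA levels; default
#'   `1, 2, ...`.
#' @return list with `statistic` (1-df chi-squared), `p_value`, `levels`,
#'   `scores`.
#' @export
trend_test <- function(cohort, variable, scores = NULL) {
  schema <- cohort_schema(cohort)
  if (!variable %in% names(schema))
    stop("'", variable, "' is not a schema covariate")
  frame <- covariate_frame(cohort)
  x <- as.character(frame[[variable]])
  y <- cohort_cases(cohort)$surgery_class == "mastectomy"
  keep <- x != "NA"
  lev <- schema[[variable]][schema[[variable]] %in% unique(x[keep])]
  if (length(lev) < 2) stop("trend test needs >= 2 ordered levels with cases")
  if (is.null(scores)) scores <- seq_along(lev)
  stopifnot(length(scores) == length(lev))
  n <- vapply(lev, function(l) sum(x == l), numeric(1))
  ev <- vapply(lev, function(l) sum(y[x == l]), numeric(1))
  if (sum(ev) == 0 || sum(ev) == sum(n)) stop("degenerate table: no variation")
  # prop.trend.test warns via its internal lm on degenerate/perfect tables;
  # the chi-squared statistic itself is well defined there
  tt <- suppressWarnings(stats::prop.trend.test(ev, n, score = scores))
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       levels = lev, scores = scores)
}
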