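# Synthetic registry generator. Emulates a one-row-per-patient case listing of
# women age >= 40 with mixed in situ / invasive disease, a covariate-driven
# mastectomy assignment model, and latent overdiagnosis labels that are
# conditionally independent of surgery given covariates (the exchangeability
# assumption holds by construction when `exchangeability_violation_delta = 0`).
# Overdiagnosis probability is masked to zero for any case meeting the
# rule-out criteria, so no generated overdiagnosis carries disqualifying
# characteristics.

#' Default generating models for the synthetic scenario
#'
#' Log-odds models over the derived covariate categories. The mastectomy model
#' is calibrated so the marginal mastectomy rate is close to 34%, increasing
#' in tumour size and decreasing in age; the overdiagnosis model concentrates
#' overdiagnosis on early, small, node-negative, in situ patterns.
#'
#' @return list with `intercept` and `coef` (named list: covariate -> named
#'   numeric vector of per-level log-odds shifts; levels absent from the
#'   vector, including `"NA"`, contribute 0).
#' @export
default_mastectomy_model <- function() {
  list(
    intercept = -0.97,
    coef = list(
      size_group  = c("0.0-0.9" = 0, "1.0-1.9" = 0.25, "2.0-2.9" = 0.65,
                      "3.0-3.9" = 0.9, "4.0-4.9" = 1.15, "5.0+" = 1.6,
                      "NA" = -0.1),
      age_group   = c("40-49" = 0, "50-64" = -0.45, "65-84" = -0.65,
                      "85+" = -0.9),
      nodes_group = c("0" = 0, "1" = 0.35, "2+" = 0.9, "NA" = -1.2),
      stage       = c("0" = 0, "I" = 0.05, "II" = 0.3, "III" = 0.8,
                      "IV" = -0.8, "NA" = -0.5),
      grade       = c("I" = 0, "II" = 0.2, "III" = 0.35, "IV" = 0.3,
                      "NA" = -0.2),
      her2        = c("pos" = 0.25, "neg" = 0, "NA" = -0.15),
      behavior    = c("in_situ" = 0, "invasive" = 0.1)
    )
  )
}

#' @rdname default_mastectomy_model
#' @export
default_overdiagnosis_model <- function() {
  list(
    intercept = -1.1,
    coef = list(
      behavior    = c("in_situ" = 1.3, "invasive" = 0),
      size_group  = c("0.0-0.9" = 0.8, "1.0-1.9" = 0.2, "2.0-2.9" = -0.6,
                      "3.0-3.9" = -1.2, "4.0-4.9" = -4, "5.0+" = -4,
                      "NA" = 0.2),
      age_group   = c("40-49" = -0.6, "50-64" = -0.2, "65-84" = 0.2,
                      "85+" = 0.8),
      nodes_group = c("0" = 0.3, "1" = -1.5, "2+" = -4, "NA" = 0.2),
      grade       = c("I" = 0.4, "II" = 0, "III" = -0.6, "IV" = -0.6,
                      "NA" = 0)
    )
  )
}

default_covariate_params <- function() {
  list(
    age_bin_probs   = c("40-49" = 0.169, "50-64" = 0.395, "65-84" = 0.387,
                        "85+" = 0.049),
    in_situ_prob    = 0.21,
    dcis_share      = 0.856,     # of in situ cases
    size_meanlog    = c(in_situ = log(1.1), invasive = log(1.8)),
    size_sdlog      = c(in_situ = 0.6, invasive = 0.65),
    size_na_prob    = 0.12,
    nodes_probs     = c(0.62, 0.12, 0.08, 0.05, 0.03),  # 0..4+, invasive
    nodes_na_prob   = 0.20,
    fascia_prob     = c(small = 0.005, large = 0.08),   # invasive, by size >= 3
    skin_prob       = 0.015,
    metastasis_prob = 0.055,
    grade_probs     = list(in_situ = c(I = 0.30, II = 0.40, III = 0.24,
                                       IV = 0.0, "NA" = 0.06),
                           invasive = c(I = 0.20, II = 0.40, III = 0.30,
                                        IV = 0.01, "NA" = 0.09)),
    her2_probs      = c(pos = 0.11, neg = 0.66, "NA" = 0.23),
    hr_probs        = c(pos = 0.72, neg = 0.11, "NA" = 0.17),
    region_probs    = c(san_francisco = 0.18, connecticut = 0.14,
                        detroit = 0.15, hawaii = 0.04, iowa = 0.11,
                        new_mexico = 0.07, seattle = 0.17, utah = 0.08,
                        atlanta = 0.06),
    race_probs      = c(white = 0.770, black = 0.111, asian_pacific = 0.106,
                        amerind_alaska = 0.007, other_unknown = 0.006),
    nonmast_surgery_probs = c(bcs = 0.85, other = 0.02, none = 0.13)
  )
}

#' Synthetic scenario configuration
#'
#' @param n_cases number of cases to generate (> 0).
#' @param seed integer master seed; per-covariate sub-streams are derived from
#'   it, so all randomness hangs off this one value.
#' @param exchangeability_violation_delta log-odds shift added to the
#'   mastectomy model when a case is overdiagnosed. 0 (the default) makes
#'   overdiagnosed and nonoverdiagnosed cases exactly exchangeable given
#'   covariates.
#' @param mastectomy_model,overdiagnosis_model log-odds models as returned by
#'   [default_mastectomy_model()] / [default_overdiagnosis_model()].
#' @param mask_criteria `ruleout_criteria` applied as a mask: cases meeting any
#'   criterion get overdiagnosis probability 0.
#' @param covariate_params marginal distributions of the generated covariates.
#' @param schema covariate schema of the resulting cohort.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 5000L, seed = 1L,
                             exchangeability_violation_delta = 0,
                             mastectomy_model = default_mastectomy_model(),
                             overdiagnosis_model = default_overdiagnosis_model(),
                             mask_criteria = ruleout_criteria(),
                             covariate_params = default_covariate_params(),
                             schema = default_covariate_schema()) {
  stopifnot(n_cases > 0)
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 delta = exchangeability_violation_delta,
                 mastectomy_model = mastectomy_model,
                 overdiagnosis_model = overdiagnosis_model,
                 mask_criteria = mask_criteria,
                 covariate_params = covariate_params,
                 schema = schema),
            class = "synthetic_config")
}

# Deterministic sub-stream seed per generation block, derived from the master
# seed, so adding a block does not perturb earlier ones.
block_seed <- function(seed, block) {
  (abs(seed) + 7919 * block) %% 2147483647
}

# Linear predictor of a log-odds model on the derived covariate frame.
model_linear_predictor <- function(frame, model) {
  lp <- rep(model$intercept, nrow(frame))
  for (nm in names(model$coef)) {
    if (!nm %in% names(frame))
      stop("model covariate '", nm, "' not in schema: inconsistent schema")
    coefs <- model$coef[[nm]]
    lvl <- as.character(frame[[nm]])
    add <- coefs[lvl]
    add[is.na(add)] <- 0
    lp <- lp + add
  }
  unname(lp)
}

#' Generate a synthetic registry cohort with known ground truth
#'
#' Deterministic given the config seed. The returned cohort carries the latent
#' `overdiagnosed` flag and hidden ground-truth columns `.true_p`
#' (the marginal mastectomy probability given covariates) and `.true_p_v`
#' (the post-mask overdiagnosis probability).
#'
#' @param config a [synthetic_config()].
#' @return a `cohort`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cases
  cp <- config$covariate_params
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  draw <- function(block, expr) {
    set.seed(block_seed(config$seed, block))
    expr
  }

  age_bin <- draw(1, sample(names(cp$age_bin_probs), n, TRUE, cp$age_bin_probs))
  age_lo <- c("40-49" = 40, "50-64" = 50, "65-84" = 65, "85+" = 85)[age_bin]
  age_hi <- c("40-49" = 49, "50-64" = 64, "65-84" = 84, "85+" = 99)[age_bin]
  age <- draw(2, as.integer(age_lo + floor(stats::runif(n) * (age_hi - age_lo + 1))))

  behavior <- draw(3, ifelse(stats::runif(n) < cp$in_situ_prob,
                             "in_situ", "invasive"))
  in_situ <- behavior == "in_situ"

  histology <- draw(4, {
    h <- integer(n)
    dcis_codes <- dcis_histology_codes()
    is_dcis <- stats::runif(n) < cp$dcis_share
    h[in_situ & is_dcis] <- sample(dcis_codes, sum(in_situ & is_dcis), TRUE,
                                   prob = c(2, 2, 70, rep(2, 7), 12) / 100)
    h[in_situ & !is_dcis] <- 8520L
    h[!in_situ] <- sample(c(8500L, 8520L, 8480L, 8010L), sum(!in_situ), TRUE,
                          prob = c(0.75, 0.12, 0.05, 0.08))
    h
  })

  size <- draw(5, {
    s <- stats::rlnorm(n,
                       meanlog = cp$size_meanlog[ifelse(in_situ, "in_situ", "invasive")],
                       sdlog = cp$size_sdlog[ifelse(in_situ, "in_situ", "invasive")])
    s <- pmax(0.1, pmin(round(s, 1), 9.9))
    s[stats::runif(n) < cp$size_na_prob] <- NA_real_
    s
  })

  nodes <- draw(6, {
    k <- integer(n)
    inv <- which(!in_situ)
    k[inv] <- sample(seq_along(cp$nodes_probs) - 1L, length(inv), TRUE,
                     cp$nodes_probs)
    k[stats::runif(n) < cp$nodes_na_prob] <- NA_integer_
    k[in_situ & !is.na(k)] <- 0L
    k
  })

  flags <- draw(7, {
    large <- !is.na(size) & size >= 3
    fascia <- !in_situ & stats::runif(n) <
      ifelse(large, cp$fascia_prob[["large"]], cp$fascia_prob[["small"]])
    skin <- !in_situ & stats::runif(n) < cp$skin_prob
    mets <- !in_situ & stats::runif(n) < cp$metastasis_prob
    list(fascia = fascia, skin = skin, mets = mets)
  })

  grade <- draw(8, {
    g <- character(n)
    for (b in c("in_situ", "invasive")) {
      idx <- which((behavior == b))
      pr <- cp$grade_probs[[b]]
      g[idx] <- sample(names(pr), length(idx), TRUE, pr)
    }
    g
  })

  her2 <- draw(9, sample(names(cp$her2_probs), n, TRUE, cp$her2_probs))
  hr   <- draw(10, sample(names(cp$hr_probs), n, TRUE, cp$hr_probs))

  stage <- ifelse(in_situ, "0",
           ifelse(flags$mets, "IV",
           ifelse((!is.na(nodes) & nodes >= 2) | (!is.na(size) & size >= 5), "III",
           ifelse((!is.na(nodes) & nodes == 1) | (!is.na(size) & size >= 2), "II",
           ifelse(is.na(size) & is.na(nodes), "NA", "I")))))

  region <- draw(11, sample(names(cp$region_probs), n, TRUE, cp$region_probs))
  race   <- draw(12, sample(names(cp$race_probs), n, TRUE, cp$race_probs))

  cases <- data.frame(
    case_id = sprintf("case%06d", seq_len(n)),
    age_years = age, stage = stage, tumor_size_cm = size,
    nodes_positive = nodes, grade = grade, her2 = her2, hr = hr,
    histology_icdo3 = histology, behavior = behavior,
    invades_fascia_muscle_chestwall = flags$fascia,
    skin_ulceration_or_adjacent_skin = flags$skin,
    distant_metastasis = flags$mets,
    surgery_class = "none", region = region, race = race,
    stringsAsFactors = FALSE
  )

  # latent overdiagnosis, masked to zero where rule-out criteria trigger
  tmp_cohort <- new_cohort(cases, config$schema)
  frame <- covariate_frame(tmp_cohort)
  p_v <- stats::plogis(model_linear_predictor(frame, config$overdiagnosis_model))
  p_v[is_ruled_out(cases, config$mask_criteria)] <- 0
  overdiagnosed <- draw(13, stats::runif(n) < p_v)

  lp_m <- model_linear_predictor(frame, config$mastectomy_model)
  p_m_given_v <- stats::plogis(lp_m + config$delta * overdiagnosed)
  mast <- draw(14, stats::runif(n) < p_m_given_v)
  surgery <- draw(15, ifelse(mast, "mastectomy",
                             sample(names(cp$nonmast_surgery_probs), n, TRUE,
                                    cp$nonmast_surgery_probs)))

  cases$surgery_class <- surgery
  cases$overdiagnosed <- overdiagnosed
  # Pr(M | X) marginalized over the latent label (equals plogis(lp_m) at delta=0)
  cases$.true_p <- round((1 - p_v) * stats::plogis(lp_m) +
                         p_v * stats::plogis(lp_m + config$delta), 8)
  cases$.true_p_v <- round(p_v, 8)
  new_cohort(cases, config$schema)
}

#' Realized overtreatment rate of a synthetic cohort
#'
#' The fraction of all cases that are both overdiagnosed and treated by
#' mastectomy — the estimand the fill-up bounds bracket.
#'
#' @param cohort a `cohort` with `overdiagnosed` flags.
#' @return fraction in [0, 1].
#' @export
true_overtreatment_rate <- function(cohort) {
  cases <- cohort_cases(cohort)
  if (!"overdiagnosed" %in% names(cases) || anyNA(cases$overdiagnosed))
    stop("cohort has no complete overdiagnosed flags (not a synthetic cohort?)")
  mean(cases$surgery_class == "mastectomy" & cases$overdiagnosed)
}

#' Ground-truth propensities from the generating model
#'
#' Recomputes Pr(mastectomy | X) from the generating log-odds model (averaged
#' over the latent overdiagnosis label when the exchangeability violation is
#' nonzero). These are model probabilities, not fitted values.
#'
#' @param cohort a synthetic `cohort`.
#' @param config the `synthetic_config` that generated it.
#' @return a `propensity_estimates` with tag `"oracle"`.
#' @export
true_propensities <- function(cohort, config) {
  frame <- covariate_frame(cohort)
  cases <- cohort_cases(cohort)
  lp_m <- model_linear_predictor(frame, config$mastectomy_model)
  p_v <- stats::plogis(model_linear_predictor(frame, config$overdiagnosis_model))
  p_v[is_ruled_out(cases, config$mask_criteria)] <- 0
  p <- (1 - p_v) * stats::plogis(lp_m) + p_v * stats::plogis(lp_m + config$delta)
  structure(data.frame(case_id = cases$case_id, p_hat = p, tag = "oracle",
                       stringsAsFactors = FALSE),
            class = c("propensity_estimates", "data.frame"),
            spec = model_spec("oracle"))
}

# ---- YAML scenario presets ----------------------------------------------------

#' Load a synthetic scenario preset from YAML
#'
#' Recognized fields: `n_cases`, `seed`, `exchangeability_violation_delta`,
#' and optional `mastectomy_model` / `overdiagnosis_model` blocks with an
#' `intercept` and a `coef` map (covariate -> level -> log-odds). Omitted
#' fields keep the package defaults. Two presets ship with the package under
#' `system.file("extdata", ...)`: `scenario_default.yaml` (exchangeability
#' holds) and `scenario_violation.yaml` (a positive log-odds shift toward
#' mastectomy for overdiagnosed cases).
#'
#' @param path YAML file path.
#' @return a [synthetic_config()].
#' @export
synthetic_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("n_cases", "seed", "exchangeability_violation_delta"))]
  as_model <- function(block, default) {
    if (is.null(block)) return(default)
    list(intercept = if (is.null(block$intercept)) default$intercept
                     else block$intercept,
         coef = if (is.null(block$coef)) default$coef
                else lapply(block$coef, function(v) unlist(v)))
  }
  args$mastectomy_model <- as_model(y$mastectomy_model,
                                    default_mastectomy_model())
  args$overdiagnosis_model <- as_model(y$overdiagnosis_model,
                                       default_overdiagnosis_model())
  do.call(synthetic_config, args)
}
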