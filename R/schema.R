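# Covariate schema: which case characteristics enter the propensity model and
# the descriptive tables, and the category levels of each. "NA" is always an
# explicit level — missingness in registry data can be informative of surgical
# choice, so nothing is ever imputed.

#' Default covariate schema
#'
#' The default predictor set mirrors the standard registry case-listing
#' variables: AJCC stage, tumour size and positive-node categories, grade,
#' HER2 and hormone-receptor status, behaviour, age group, registry region and
#' race. Additional categorical covariates present in a case listing can be
#' added via `extra`.
#'
#' @param extra named list of character vectors: extra categorical covariates
#'   and their levels (excluding the `"NA"` level, which is always appended).
#' @return an object of class `covariate_schema`: a named list of level
#'   vectors, each carrying an implicit final `"NA"` level.
#' @export
default_covariate_schema <- function(extra = list()) {
  base <- list(
    stage       = c("0", "I", "II", "III", "IV"),
    size_group  = c("0.0-0.9", "1.0-1.9", "2.0-2.9", "3.0-3.9", "4.0-4.9", "5.0+"),
    nodes_group = c("0", "1", "2+"),
    grade       = c("I", "II", "III", "IV"),
    her2        = c("pos", "neg"),
    hr          = c("pos", "neg"),
    behavior    = c("in_situ", "invasive"),
    age_group   = c("40-49", "50-64", "65-84", "85+"),
    region      = c("san_francisco", "connecticut", "detroit", "hawaii", "iowa",
                    "new_mexico", "seattle", "utah", "atlanta"),
    race        = c("white", "black", "asian_pacific", "amerind_alaska", "other_unknown")
  )
  stopifnot(is.list(extra))
  if (length(extra)) {
    if (is.null(names(extra)) || any(names(extra) == ""))
      stop("extra covariates must be named")
    base <- c(base, extra)
  }
  structure(base, class = "covariate_schema")
}

#' @export
print.covariate_schema <- function(x, ...) {
  cat("Covariate schema with", length(x), "covariates:\n")
  for (nm in names(x))
    cat(" ", nm, ": ", paste(x[[nm]], collapse = ", "), ", NA\n", sep = "")
  invisible(x)
}

# Derived categorical recodings used by the schema. Bin edges follow the
# conventional registry table layout.
age_group_of <- function(age_years) {
  cut(age_years, breaks = c(40, 50, 65, 85, Inf), right = FALSE,
      labels = c("40-49", "50-64", "65-84", "85+"))
}

size_group_of <- function(tumor_size_cm) {
  out <- cut(tumor_size_cm, breaks = c(0, 1, 2, 3, 4, 5, Inf), right = FALSE,
             labels = c("0.0-0.9", "1.0-1.9", "2.0-2.9", "3.0-3.9", "4.0-4.9", "5.0+"))
  as.character(out)
}

nodes_group_of <- function(nodes_positive) {
  ifelse(is.na(nodes_positive), NA_character_,
         ifelse(nodes_positive >= 2, "2+", as.character(nodes_positive)))
}

# Build the factor frame the models see: one factor column per schema
# covariate, with "NA" as an explicit final level.
covariate_frame <- function(cohort, schema = cohort_schema(cohort)) {
  cases <- cohort_cases(cohort)
  out <- lapply(names(schema), function(nm) {
    vals <- switch(nm,
      age_group   = as.character(age_group_of(cases$age_years)),
      size_group  = size_group_of(cases$tumor_size_cm),
      nodes_group = nodes_group_of(cases$nodes_positive),
      {
        if (!nm %in% names(cases))
          stop("covariate '", nm, "' in schema but not in cohort")
        as.character(cases[[nm]])
      })
    vals[is.na(vals) | vals == "NA"] <- "NA"
    bad <- setdiff(unique(vals), c(schema[[nm]], "NA"))
    if (length(bad))
      stop("covariate '", nm, "' has values outside its schema levels: ",
           paste(bad, collapse = ", "))
    factor(vals, levels = c(schema[[nm]], "NA"))
  })
  names(out) <- names(schema)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Default surgery code map
#'
#' Maps registry surgery descriptors to the four analysis classes. Total
#' mastectomy comprises simple and modified radical mastectomy;
#' breast-conserving surgery comprises lumpectomy and related partial
#' resections; subcutaneous mastectomy and other procedures are "other"; no
#' surgery of the primary site is "none".
#'
#' @return named character vector: registry code -> surgery class.
#' @export
default_surgery_code_map <- function() {
  c(
    "simple mastectomy"             = "mastectomy",
    "modified radical mastectomy"   = "mastectomy",
    "lumpectomy"                    = "bcs",
    "excisional biopsy"             = "bcs",
    "segmental mastectomy"          = "bcs",
    "subtotal mastectomy"           = "bcs",
    "quadrantectomy"                = "bcs",
    "tylectomy"                     = "bcs",
    "wedge resection"               = "bcs",
    "nipple resection"              = "bcs",
    "partial mastectomy nos"        = "bcs",
    "subcutaneous mastectomy"       = "other",
    "other surgery"                 = "other",
    "no surgery"                    = "none"
  )
}

#' Classify raw registry surgery codes
#'
#' @param raw_code character vector of registry surgery descriptors.
#' @param code_map named character vector mapping codes to classes; defaults to
#'   [default_surgery_code_map()].
#' @return character vector over `{mastectomy, bcs, other, none}`.
#' @export
classify_surgery <- function(raw_code, code_map = default_surgery_code_map()) {
  stopifnot(is.character(code_map), !is.null(names(code_map)))
  if (!all(code_map %in% c("mastectomy", "bcs", "other", "none")))
    stop("code map values must be mastectomy, bcs, other or none")
  unknown <- setdiff(unique(raw_code), names(code_map))
  if (length(unknown))
    stop("unknown surgery code(s): ", paste(unknown, collapse = ", "))
  unname(code_map[raw_code])
}
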