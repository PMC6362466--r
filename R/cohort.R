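# Cohort container: a validated data.frame of registry cases plus the
# covariate schema and the exclusion report produced at read time.

SURGERY_CLASSES <- c("mastectomy", "bcs", "other", "none")
STAGE_LEVELS    <- c("0", "I", "II", "III", "IV", "NA")
GRADE_LEVELS    <- c("I", "II", "III", "IV", "NA")
POSNEG_LEVELS   <- c("pos", "neg", "NA")
BEHAVIOR_LEVELS <- c("in_situ", "invasive")

# Core case columns in canonical order. Extra covariates and synthetic
# ground-truth columns (overdiagnosed, .true_p etc.) follow these.
CASE_COLUMNS <- c(
  "case_id", "age_years", "stage", "tumor_size_cm", "nodes_positive", "grade",
  "her2", "hr", "histology_icdo3", "behavior",
  "invades_fascia_muscle_chestwall", "skin_ulceration_or_adjacent_skin",
  "distant_metastasis", "surgery_class", "region", "race"
)

#' Construct a cohort
#'
#' @param cases data.frame with one row per case; see the package README for
#'   the column contract. Categorical missingness is encoded as the string
#'   `"NA"`; numeric/boolean missingness as `NA`.
#' @param schema a `covariate_schema`; defaults to [default_covariate_schema()].
#' @param exclusion_report optional list of exclusion counts (attached by
#'   [read_cohort()]).
#' @return object of class `cohort`.
#' @export
new_cohort <- function(cases, schema = default_covariate_schema(),
                       exclusion_report = NULL) {
  obj <- structure(list(cases = cases, schema = schema,
                        exclusion_report = exclusion_report),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

validate_cohort <- function(cohort) {
  cases <- cohort$cases
  stopifnot(is.data.frame(cases))
  missing_cols <- setdiff(CASE_COLUMNS, names(cases))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(cases$case_id))
    stop("duplicate case_id: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "))
  check_in <- function(col, levels) {
    bad <- !(cases[[col]] %in% levels)
    if (any(bad))
      stop("invalid ", col, " value(s): ",
           paste(unique(cases[[col]][bad]), collapse = ", "))
  }
  if (nrow(cases)) {
    if (any(is.na(cases$age_years)) || any(cases$age_years < 40))
      stop("age_years must be >= 40 in a validated cohort")
    check_in("stage", STAGE_LEVELS)
    check_in("grade", GRADE_LEVELS)
    check_in("her2", POSNEG_LEVELS)
    check_in("hr", POSNEG_LEVELS)
    check_in("behavior", BEHAVIOR_LEVELS)
    check_in("surgery_class", SURGERY_CLASSES)
    if (any(cases$tumor_size_cm < 0, na.rm = TRUE))
      stop("tumor_size_cm must be NA or >= 0")
    if (any(cases$nodes_positive < 0, na.rm = TRUE))
      stop("nodes_positive must be NA or >= 0")
  }
  # schema must be resolvable against the cases
  covariate_frame(cohort)
  invisible(cohort)
}

#' @rdname new_cohort
#' @param cohort a `cohort` object.
#' @export
cohort_cases <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$cases
}

#' @rdname new_cohort
#' @export
cohort_schema <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  cohort$schema
}

#' @rdname new_cohort
#' @export
n_cases <- function(cohort) nrow(cohort_cases(cohort))

#' @rdname new_cohort
#' @export
exclusion_report <- function(cohort) cohort$exclusion_report

#' @export
print.cohort <- function(x, ...) {
  cases <- cohort_cases(x)
  cat("Cohort of", nrow(cases), "cases")
  if (nrow(cases)) {
    pm <- mean(cases$surgery_class == "mastectomy")
    cat(sprintf(" (%.1f%% mastectomy, %.1f%% in situ)",
                100 * pm, 100 * mean(cases$behavior == "in_situ")))
  }
  cat("\n")
  if (!is.null(x$exclusion_report)) {
    er <- x$exclusion_report
    cat("Read-time exclusions: age <40:", er$age_excluded,
        "| unknown surgery:", er$surgery_excluded, "\n")
  }
  if ("overdiagnosed" %in% names(cases))
    cat("Latent overdiagnosis labels present (synthetic cohort)\n")
  invisible(x)
}

#' Take a row subset of a cohort
#'
#' @param cohort a `cohort`.
#' @param idx logical or integer row index.
#' @return a `cohort` over the selected cases (schema preserved).
#' @export
subset_cohort <- function(cohort, idx) {
  new_cohort(cohort_cases(cohort)[idx, , drop = FALSE], cohort_schema(cohort))
}

# ---- CSV reader/writer -----------------------------------------------------
# Encoding contract: comma-separated, UTF-8, header row; categorical NA as the
# literal "NA"; booleans as "0"/"1"; numeric NA as "NA".

parse_field <- function(raw, field, kind, row_ids) {
  raw <- trimws(raw)
  miss <- raw == "NA" | raw == ""
  fail <- function(bad) {
    stop("malformed row ", row_ids[which(bad)[1]], ": field '", field,
         "' has invalid value '", raw[which(bad)[1]], "'")
  }
  if (kind == "numeric") {
    out <- suppressWarnings(as.numeric(raw))
    bad <- !miss & is.na(out)
    if (any(bad)) fail(bad)
    out[miss] <- NA_real_
    out
  } else if (kind == "integer") {
    out <- suppressWarnings(as.integer(raw))
    bad <- !miss & (is.na(out) | out != suppressWarnings(as.numeric(raw)))
    if (any(bad)) fail(bad)
    out[miss] <- NA_integer_
    out
  } else if (kind == "boolean") {
    out <- rep(NA, length(raw))
    out[raw == "1"] <- TRUE
    out[raw == "0"] <- FALSE
    bad <- !miss & !(raw %in% c("0", "1"))
    if (any(bad)) fail(bad)
    out
  } else { # categorical: keep "NA" literal as the level string
    raw[miss] <- "NA"
    raw
  }
}

case_field_kinds <- function() c(
  case_id = "categorical", age_years = "integer", stage = "categorical",
  tumor_size_cm = "numeric", nodes_positive = "integer", grade = "categorical",
  her2 = "categorical", hr = "categorical", histology_icdo3 = "integer",
  behavior = "categorical", invades_fascia_muscle_chestwall = "boolean",
  skin_ulceration_or_adjacent_skin = "boolean", distant_metastasis = "boolean",
  surgery_class = "categorical", region = "categorical", race = "categorical",
  overdiagnosed = "boolean", .true_p = "numeric", .true_p_v = "numeric"
)

#' Read a registry case listing from CSV
#'
#' Rows with age below 40 or with surgery class outside
#' `{mastectomy, bcs, other, none}` are dropped (not errors) and counted in the
#' cohort's exclusion report, mirroring the eligibility filtering applied to
#' registry data. Any other malformed field is an error naming the row and
#' field. Duplicate case ids are an error.
#'
#' @param path CSV file path.
#' @param schema covariate schema the cohort must satisfy.
#' @return a `cohort`; its [exclusion_report()] lists `age_excluded`,
#'   `surgery_excluded`, `retained` and `input_rows`.
#' @export
read_cohort <- function(path, schema = default_covariate_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  kinds <- case_field_kinds()
  missing_cols <- setdiff(CASE_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("header is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  row_ids <- seq_len(nrow(raw)) + 1L  # header is line 1
  cases <- as.data.frame(
    lapply(stats::setNames(names(raw), names(raw)), function(col) {
      kind <- if (col %in% names(kinds)) kinds[[col]] else "categorical"
      parse_field(raw[[col]], col, kind, row_ids)
    }),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (anyDuplicated(cases$case_id))
    stop("duplicate case_id: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "))
  if (any(is.na(cases$age_years)))
    stop("malformed row ", row_ids[which(is.na(cases$age_years))[1]],
         ": field 'age_years' is missing")
  age_drop <- cases$age_years < 40
  surg_drop <- !age_drop & !(cases$surgery_class %in% SURGERY_CLASSES)
  report <- list(input_rows = nrow(cases),
                 age_excluded = sum(age_drop),
                 surgery_excluded = sum(surg_drop),
                 retained = sum(!age_drop & !surg_drop))
  new_cohort(cases[!age_drop & !surg_drop, , drop = FALSE], schema,
             exclusion_report = report)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: NA encoded as the literal `"NA"`, booleans as
#' `"0"`/`"1"`.
#'
#' @param cohort a `cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cases <- cohort_cases(cohort)
  out <- as.data.frame(
    lapply(cases, function(col) {
      if (is.logical(col)) {
        enc <- ifelse(col, "1", "0")
      } else if (is.numeric(col)) {
        enc <- vapply(col, function(v) {
          if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE)
        }, character(1))
        enc
      } else {
        enc <- as.character(col)
      }
      enc[is.na(enc)] <- "NA"
      enc
    }),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
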