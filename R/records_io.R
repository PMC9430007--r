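# Data model and delimited-file I/O for the three input tables:
# studies.csv (one row per reproduced study), covariates.csv (study x
# covariate x arm prevalences), checklist.csv (study x 54 reporting items).
#
# One CSV dialect only: UTF-8, comma separator, "." decimal point, required
# header, absent numeric values encoded as the empty string (never 0 --
# absence is meaningful, e.g. unreported p-values). Effect estimates are
# stored on the ratio scale; logs are taken at computation time, never at
# I/O time.

ASSUMPTION_CATEGORIES <- c(
  "index_date", "inclusion_exclusion", "exposure",
  "outcome", "follow_up", "covariates"
)

# Canonical studies.csv layout: a fixed two-arm wide format. The exposure
# arm uses suffix `_exp`, the reference arm `_ref` (listed last, giving rate
# comparisons a stable reference). Descriptive studies use only the `_exp`
# block and have no effect estimate.
studies_columns <- function() {
  arm_block <- function(version) {
    unlist(lapply(c("exp", "ref"), function(arm) {
      paste0(version, "_", c("n", "events", "risk", "rate", "py"), "_", arm)
    }))
  }
  eff_block <- function(version) paste0(version, "_", c("est", "ci_low", "ci_high", "p"))
  c(
    "study_id", "design", "measure",
    arm_block("orig"), eff_block("orig"),
    arm_block("repro"), eff_block("repro"),
    "funding_source", "data_source", "publication_year",
    "journal_impact_band", "author_responsive", "same_group"
  )
}

covariates_columns <- function() {
  c("study_id", "covariate", "arm", "prev_original_pct", "prev_reproduction_pct")
}

checklist_columns <- function() {
  c(
    "study_id", "design", sprintf("item_%02d", 1:54),
    paste0("assume_", ASSUMPTION_CATEGORIES)
  )
}

# type map: "c" character, "l" logical, "d" double
studies_type_map <- function() {
  chr <- c(
    "study_id", "design", "measure", "funding_source", "data_source",
    "journal_impact_band"
  )
  lgl <- c("author_responsive", "same_group")
  cols <- studies_columns()
  setNames(ifelse(cols %in% chr, "c", ifelse(cols %in% lgl, "l", "d")), cols)
}

covariates_type_map <- function() {
  setNames(c("c", "c", "c", "d", "d"), covariates_columns())
}

checklist_type_map <- function() {
  cols <- checklist_columns()
  setNames(ifelse(startsWith(cols, "assume_"), "l", "c"), cols)
}

# Convert character columns to their declared types. Doubles go through
# as.numeric (correctly-rounded strtod) so that write -> read -> write is
# byte-identical at full double precision.
apply_type_map <- function(raw, type_map) {
  for (col in names(type_map)) {
    raw[[col]] <- switch(type_map[[col]],
      c = as.character(raw[[col]]),
      l = as.logical(raw[[col]]),
      d = as.numeric(raw[[col]])
    )
  }
  raw
}

#' Construct a ratio-scale effect estimate
#'
#' A measure of association (hazard ratio, risk ratio, or odds ratio) with an
#' optional 95% confidence interval and p-value. The null value on this scale
#' is 1.0.
#'
#' @param point Point estimate, a positive real on the ratio scale.
#' @param ci_low,ci_high Optional 95% CI bounds; must satisfy
#'   `0 < ci_low <= point <= ci_high`.
#' @param p_value Optional two-sided p-value in `[0, 1]`.
#' @param measure One of `"HR"`, `"RR"`, `"OR"`.
#' @return An object of class `effect_estimate`.
#' @export
#' @examples
#' effect_estimate(1.4, 1.1, 1.8)
effect_estimate <- function(point, ci_low = NA_real_, ci_high = NA_real_,
                            p_value = NA_real_, measure = "HR") {
  if (!is.numeric(point) || length(point) != 1L || is.na(point) || point <= 0) {
    abort("`point` must be a single positive number (ratio scale).")
  }
  measure <- match.arg(measure, c("HR", "RR", "OR"))
  has_ci <- !is.na(ci_low) || !is.na(ci_high)
  if (has_ci) {
    if (is.na(ci_low) || is.na(ci_high)) {
      abort("Provide both `ci_low` and `ci_high`, or neither.")
    }
    if (ci_low <= 0 || ci_low > point || ci_high < point) {
      abort("CI must satisfy 0 < ci_low <= point <= ci_high.")
    }
  }
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    abort("`p_value` must lie in [0, 1].")
  }
  structure(
    list(point = point, ci_low = as.numeric(ci_low),
         ci_high = as.numeric(ci_high), p_value = as.numeric(p_value),
         measure = measure),
    class = "effect_estimate"
  )
}

#' Construct a single study-arm result
#'
#' Holds the cohort size and outcome occurrence for one exposure arm. Rates
#' are normalised to events per 100 person-years at construction time; a
#' source table reporting rates per 1,000 person-years passes
#' `rate_denominator = 1000`.
#'
#' @param n Number of subjects (non-negative integer).
#' @param events Optional outcome event count, `events <= n`.
#' @param risk_pct Optional outcome risk in percent (`[0, 100]`).
#' @param rate Optional outcome rate, per `rate_denominator` person-years.
#' @param person_years Optional total follow-up time in person-years.
#' @param rate_denominator Person-years denominator of `rate` as given in the
#'   source (default 100).
#' @param arm_id Arm label.
#' @return An object of class `arm_result` with `rate_per100py` normalised.
#' @export
arm_result <- function(n, events = NA_real_, risk_pct = NA_real_,
                       rate = NA_real_, person_years = NA_real_,
                       rate_denominator = 100, arm_id = "exp") {
  if (is.na(n) || n < 0) abort("`n` must be a non-negative count.")
  if (!is.na(events) && (events < 0 || events > n)) {
    abort("`events` must satisfy 0 <= events <= n.")
  }
  if (!is.na(risk_pct) && (risk_pct < 0 || risk_pct > 100)) {
    abort("`risk_pct` must lie in [0, 100].")
  }
  rate100 <- if (is.na(rate)) NA_real_ else rate * 100 / rate_denominator
  if (!is.na(rate100) && rate100 < 0) abort("rate must be non-negative.")
  if (!is.na(person_years) && person_years < 0) {
    abort("`person_years` must be non-negative.")
  }
  if (!is.na(events) && !is.na(person_years) && !is.na(rate100) &&
      person_years > 0) {
    implied <- 100 * events / person_years
    if (implied > 0 && abs(rate100 - implied) / implied > 0.005) {
      abort("`rate` inconsistent with 100 * events / person_years (>0.5%).")
    }
  }
  structure(
    list(arm_id = arm_id, n = n, events = as.numeric(events),
         risk_pct = as.numeric(risk_pct), rate_per100py = rate100,
         person_years = as.numeric(person_years)),
    class = "arm_result"
  )
}

# --- row-level validation ---------------------------------------------------

# Collect a character vector of violation messages for one studies-table row.
validate_study_row <- function(row) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (is.na(row$study_id) || !nzchar(row$study_id)) note("missing study_id")
  if (!isTRUE(row$design %in% c("comparative", "descriptive"))) {
    note("design must be 'comparative' or 'descriptive'")
  }

  check_arm <- function(version, arm) {
    p <- function(field) row[[paste0(version, "_", field, "_", arm)]]
    if (!is.na(p("n")) && p("n") < 0) note(sprintf("%s %s arm: n < 0", version, arm))
    if (!is.na(p("events")) && !is.na(p("n")) && p("events") > p("n")) {
      note(sprintf("%s %s arm: events > n", version, arm))
    }
    if (!is.na(p("risk")) && (p("risk") < 0 || p("risk") > 100)) {
      note(sprintf("%s %s arm: risk outside [0, 100]", version, arm))
    }
    if (!is.na(p("events")) && !is.na(p("py")) && !is.na(p("rate")) &&
        p("py") > 0) {
      implied <- 100 * p("events") / p("py")
      if (implied > 0 && abs(p("rate") - implied) / implied > 0.005) {
        note(sprintf("%s %s arm: rate inconsistent with events/person-years", version, arm))
      }
    }
  }
  check_effect <- function(version) {
    p <- function(field) row[[paste0(version, "_", field)]]
    if (!is.na(p("est")) && p("est") <= 0) {
      note(sprintf("%s effect: point estimate must be > 0", version))
    }
    has_ci <- !is.na(p("ci_low")) || !is.na(p("ci_high"))
    if (has_ci) {
      if (is.na(p("ci_low")) || is.na(p("ci_high"))) {
        note(sprintf("%s effect: one-sided CI (need both bounds)", version))
      } else if (is.na(p("est"))) {
        note(sprintf("%s effect: CI without point estimate", version))
      } else if (p("ci_low") <= 0 || p("ci_low") > p("est") ||
                 p("ci_high") < p("est")) {
        note(sprintf("%s effect: CI violates 0 < ci_low <= point <= ci_high", version))
      }
    }
    if (!is.na(p("p")) && (p("p") < 0 || p("p") > 1)) {
      note(sprintf("%s effect: p-value outside [0, 1]", version))
    }
  }

  for (version in c("orig", "repro")) {
    for (arm in c("exp", "ref")) check_arm(version, arm)
    check_effect(version)
  }

  if (isTRUE(row$design == "comparative")) {
    if (!isTRUE(row$measure %in% c("HR", "RR", "OR"))) {
      note("comparative study: measure must be HR, RR, or OR")
    }
    for (version in c("orig", "repro")) {
      if (is.na(row[[paste0(version, "_n_exp")]]) ||
          is.na(row[[paste0(version, "_n_ref")]])) {
        note(sprintf("comparative study: %s needs both arms", version))
      }
      if (is.na(row[[paste0(version, "_est")]])) {
        note(sprintf("comparative study: %s effect estimate required", version))
      }
    }
  }
  if (isTRUE(row$design == "descriptive")) {
    if (!is.na(row$orig_est) || !is.na(row$repro_est)) {
      note("descriptive study: must not carry an effect estimate")
    }
  }
  problems
}

# Split a raw studies tibble into validated records and a rejection report.
# Validation is total: every input row ends up in exactly one of the two.
validate_study_pairs <- function(raw) {
  raw$study_id <- as.character(raw$study_id)
  problems <- lapply(seq_len(nrow(raw)), function(i) {
    validate_study_row(as.list(raw[i, ]))
  })
  bad <- lengths(problems) > 0
  rejected <- tibble(
    row = which(bad),
    study_id = raw$study_id[bad],
    reason = vapply(problems[bad], paste, character(1), collapse = "; ")
  )
  list(records = raw[!bad, , drop = FALSE], rejected = rejected)
}

validate_covariates <- function(raw) {
  raw$study_id <- as.character(raw$study_id)
  ok_range <- function(x) !is.na(x) & x >= 0 & x <= 100
  reasons <- rep("", nrow(raw))
  bad_o <- !ok_range(raw$prev_original_pct)
  bad_r <- !ok_range(raw$prev_reproduction_pct)
  reasons[bad_o] <- "prev_original_pct outside [0, 100]"
  reasons[bad_r] <- trimws(paste(reasons[bad_r], "prev_reproduction_pct outside [0, 100]", sep = "; "))
  reasons <- sub("^; ", "", reasons)
  bad <- bad_o | bad_r
  list(
    records = raw[!bad, , drop = FALSE],
    rejected = tibble(row = which(bad), study_id = raw$study_id[bad],
                      reason = reasons[bad])
  )
}

validate_checklist <- function(raw) {
  raw$study_id <- as.character(raw$study_id)
  responses <- c("reported", "partially_reported", "not_reported", "not_applicable")
  item_cols <- sprintf("item_%02d", 1:54)
  problems <- lapply(seq_len(nrow(raw)), function(i) {
    row <- as.list(raw[i, ])
    out <- character()
    if (!isTRUE(row$design %in% c("comparative", "descriptive"))) {
      out <- c(out, "design must be 'comparative' or 'descriptive'")
    }
    vals <- unlist(row[item_cols], use.names = FALSE)
    if (anyNA(vals) || !all(vals %in% responses)) {
      out <- c(out, "all 54 items must carry a valid response")
    }
    if (isTRUE(row$design == "descriptive") && isTRUE(row$assume_exposure)) {
      out <- c(out, "exposure category not applicable to descriptive studies")
    }
    out
  })
  bad <- lengths(problems) > 0
  list(
    records = raw[!bad, , drop = FALSE],
    rejected = tibble(
      row = which(bad), study_id = raw$study_id[bad],
      reason = vapply(problems[bad], paste, character(1), collapse = "; ")
    )
  )
}

# --- readers / writers ------------------------------------------------------

read_validated <- function(path, type_map, validator) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  required <- names(type_map)
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(sprintf("Schema error: missing mandatory column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  raw <- apply_type_map(raw[required], type_map)
  out <- validator(raw)
  structure(as_tibble(out$records), rejected = out$rejected,
            class = c("rwe_table", class(out$records)))
}

#' Read and validate the per-study results table
#'
#' Reads `studies.csv` (one row per reproduced study; see
#' [studies_schema()] for the column dictionary), validates every row, and
#' returns the valid records. Malformed rows are never silently dropped: they
#' are collected into a rejection report retrievable with
#' [rejection_report()], so that valid rows plus rejected rows always sum to
#' the input rows.
#'
#' @param path Path to a CSV file.
#' @param schema_version Schema version label; only `"1"` is defined.
#' @return A tibble of validated study pairs with a `rejected` attribute.
#' @export
read_study_pairs <- function(path, schema_version = "1") {
  if (!identical(schema_version, "1")) {
    abort(sprintf("Unknown schema version: %s", schema_version))
  }
  read_validated(path, studies_type_map(), validate_study_pairs)
}

#' Read and validate the covariate-prevalence table
#'
#' One row per study x covariate x arm, with baseline prevalence (percent) in
#' the original publication and in the reproduction.
#'
#' @inheritParams read_study_pairs
#' @return A tibble of validated entries with a `rejected` attribute.
#' @export
read_covariates <- function(path) {
  read_validated(path, covariates_type_map(), validate_covariates)
}

#' Read and validate the reporting-clarity checklist table
#'
#' One row per study with responses to the 54 reporting items
#' (`reported` / `partially_reported` / `not_reported` / `not_applicable`)
#' and one logical flag per study-parameter category recording whether the
#' reproduction team had to make at least one assumption in that category.
#'
#' @inheritParams read_study_pairs
#' @return A tibble of validated records with a `rejected` attribute.
#' @export
read_checklist <- function(path) {
  read_validated(path, checklist_type_map(), validate_checklist)
}

#' Retrieve the rejection report of a validated table
#'
#' @param x A table returned by [read_study_pairs()], [read_covariates()],
#'   or [read_checklist()] (or a generator output, which validates clean).
#' @return A tibble with columns `row`, `study_id`, `reason`; zero rows when
#'   every input row validated.
#' @export
rejection_report <- function(x) {
  rej <- attr(x, "rejected")
  if (is.null(rej)) tibble(row = integer(), study_id = character(), reason = character()) else rej
}

write_canonical <- function(records, path, columns) {
  records <- as_tibble(records)
  for (col in setdiff(columns, names(records))) records[[col]] <- NA
  readr::write_csv(records[columns], path, na = "")
  invisible(path)
}

#' Write tables in the canonical CSV dialect
#'
#' Deterministic column order, UTF-8, `.` decimal point, absent values as
#' empty strings. Writing then re-reading validated records reproduces them
#' exactly, and write/read/write is byte-identical.
#'
#' @param records A validated tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_study_pairs <- function(records, path) {
  write_canonical(records, path, studies_columns())
}

#' @rdname write_study_pairs
#' @export
write_covariates <- function(records, path) {
  write_canonical(records, path, covariates_columns())
}

#' @rdname write_study_pairs
#' @export
write_checklist <- function(records, path) {
  write_canonical(records, path, checklist_columns())
}

#' Column dictionary of the studies table
#'
#' @return A tibble with one row per column of `studies.csv`: name, type,
#'   and a short description. Shipped machine-readable as
#'   `system.file("extdata", "studies_schema.csv", package = "rwerepro")`.
#' @export
studies_schema <- function() {
  path <- system.file("extdata", "studies_schema.csv", package = "rwerepro")
  readr::read_csv(path, col_types = "ccc", progress = FALSE)
}
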