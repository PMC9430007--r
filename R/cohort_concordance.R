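# Concordance of cohort construction: sample sizes, baseline covariate
# prevalences, outcome risks and rates. Differences are always taken
# original minus reproduction; "large" flags use a strict > 10 threshold
# (percentage points for risks/covariates, events per 100 person-years for
# rates), so a boundary difference of exactly 10 is not flagged.

#' Relative sample size (original / reproduction)
#'
#' The study sample size is the sum of the arm sizes across compared
#' exposure groups. Satisfies reciprocal symmetry: swapping original and
#' reproduction inverts the ratio.
#'
#' @param n_orig,n_repro Vectors (or scalars) of arm sizes for the original
#'   and the reproduction; `NA` entries (absent arms) are ignored.
#' @return A positive real.
#' @export
#' @examples
#' relative_sample_size(c(500, 500), c(400, 400)) # 1.25
relative_sample_size <- function(n_orig, n_repro) {
  total_o <- sum(n_orig, na.rm = TRUE)
  total_r <- sum(n_repro, na.rm = TRUE)
  if (total_r <= 0) abort("Reproduction sample size must be positive.")
  if (total_o <= 0) abort("Original sample size must be positive.")
  total_o / total_r
}

#' Baseline covariate prevalence differences
#'
#' `diff_pct = prev_original - prev_reproduction` in percentage points, with
#' a `large_flag` for `|diff| > threshold` (strict).
#'
#' @param entries A validated covariate table ([read_covariates()]).
#' @param threshold Strict flag threshold in percentage points (default 10).
#' @return The input tibble with `diff_pct` and `large_flag` columns added.
#' @export
covariate_differences <- function(entries, threshold = 10) {
  entries <- as_tibble(entries)
  prev <- c(entries$prev_original_pct, entries$prev_reproduction_pct)
  if (anyNA(prev) || any(prev < 0) || any(prev > 100)) {
    abort("Prevalences must lie in [0, 100].")
  }
  mutate(entries,
         diff_pct = prev_original_pct - prev_reproduction_pct,
         large_flag = abs(diff_pct) > threshold)
}

arm_fields <- function(arm) {
  if (inherits(arm, "arm_result")) return(arm)
  do.call(arm_result, arm)
}

#' Outcome risk difference (original - reproduction), percentage points
#'
#' Each arm's risk is taken from `risk_pct` when present, otherwise derived
#' as `100 * events / n`.
#'
#' @param orig,repro [arm_result()] objects (or lists coercible to them).
#' @return A real in `[-100, 100]`.
#' @export
risk_difference <- function(orig, repro) {
  risk_of <- function(a) {
    a <- arm_fields(a)
    if (!is.na(a$risk_pct)) return(a$risk_pct)
    if (!is.na(a$events) && a$n > 0) return(100 * a$events / a$n)
    abort("Risk unavailable: need risk_pct or events and n.")
  }
  risk_of(orig) - risk_of(repro)
}

#' Outcome rate difference (original - reproduction), per 100 person-years
#'
#' Each arm's rate is normalised to events per 100 person-years
#' ([arm_result()] performs unit conversion at construction); when absent it
#' is derived as `100 * events / person_years`.
#'
#' @inheritParams risk_difference
#' @return A real difference in events per 100 person-years.
#' @export
rate_difference <- function(orig, repro) {
  rate_of <- function(a) {
    a <- arm_fields(a)
    if (!is.na(a$rate_per100py)) return(a$rate_per100py)
    if (!is.na(a$events) && !is.na(a$person_years) && a$person_years > 0) {
      return(100 * a$events / a$person_years)
    }
    abort("Rate unavailable: need rate or events and person_years.")
  }
  rate_of(orig) - rate_of(repro)
}

#' Cohort-construction concordance tables
#'
#' Computes, for a validated portfolio: per-study relative sample sizes with
#' the extreme-ratio flag (ratio strictly below `0.5` or above `2` by
#' default); per-arm outcome risk and rate differences (one entry per
#' exposure group for comparative studies, one overall for descriptive); and,
#' when a covariate table is supplied, per-covariate prevalence differences.
#'
#' @param pairs A validated studies tibble.
#' @param covariates Optional validated covariate table.
#' @param config A [concordance_config()] (supplies the strict `> 10` flag
#'   threshold and the extreme size-ratio bounds).
#' @return A list of tibbles: `sizes`, `risks`, `rates`, and `covariates`
#'   (NULL when no covariate table was given).
#' @export
cohort_concordance_table <- function(pairs, covariates = NULL,
                                     config = concordance_config()) {
  pairs <- as_tibble(pairs)
  b <- config$size_extreme_bounds

  sizes <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    row <- pairs[i, ]
    r <- relative_sample_size(c(row$orig_n_exp, row$orig_n_ref),
                              c(row$repro_n_exp, row$repro_n_ref))
    tibble(study_id = row$study_id, design = row$design,
           rel_sample_size = r,
           size_extreme = r < b[1] | r > b[2])
  })

  arm_diff <- function(row, arm, what) {
    f <- function(version, field) row[[paste0(version, "_", field, "_", arm)]]
    mk <- function(version) {
      list(n = f(version, "n"), events = f(version, "events"),
           risk_pct = f(version, "risk"), rate = f(version, "rate"),
           person_years = f(version, "py"))
    }
    tryCatch(
      if (what == "risk") risk_difference(mk("orig"), mk("repro"))
      else rate_difference(mk("orig"), mk("repro")),
      error = function(e) NA_real_
    )
  }

  long_diffs <- function(what) {
    purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
      row <- pairs[i, ]
      arms <- if (row$design == "comparative") c("exp", "ref") else "exp"
      tibble(
        study_id = row$study_id, arm = arms,
        diff = unname(vapply(arms, function(a) arm_diff(row, a, what), numeric(1)))
      )
    }) %>%
      filter(!is.na(diff)) %>%
      mutate(large_flag = abs(diff) > config$large_diff_pct)
  }

  covs <- if (!is.null(covariates)) {
    covariate_differences(covariates, threshold = config$large_diff_pct)
  }

  list(
    sizes = sizes,
    risks = long_diffs("risk"),
    rates = long_diffs("rate"),
    covariates = covs
  )
}
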