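# Fixture builders used across the suite. Everything is generated in code;
# no fixture files on disk.

all_study_cols <- rwerepro:::studies_columns()

blank_study_row <- function() {
  chr <- c("study_id", "design", "measure", "funding_source", "data_source",
           "journal_impact_band")
  lgl <- c("author_responsive", "same_group")
  vals <- lapply(all_study_cols, function(col) {
    if (col %in% chr) NA_character_ else if (col %in% lgl) NA else NA_real_
  })
  tibble::as_tibble(stats::setNames(vals, all_study_cols))
}

# One comparative (or descriptive) study-pair row with sensible cohort
# blocks; effect CIs default to +/- 20% on the log scale around the point.
make_pair <- function(id, est_o = NULL, est_r = NULL,
                      ci_o = NULL, ci_r = NULL, p_o = NA, p_r = NA,
                      design = "comparative", measure = "HR",
                      n_o = c(500, 500), n_r = c(400, 400), ...) {
  row <- blank_study_row()
  row$study_id <- id
  row$design <- design
  if (design == "comparative") {
    row$measure <- measure
    if (is.null(ci_o)) ci_o <- exp(log(est_o) + c(-0.2, 0.2))
    if (is.null(ci_r)) ci_r <- exp(log(est_r) + c(-0.2, 0.2))
    row$orig_est <- est_o; row$orig_ci_low <- ci_o[1]; row$orig_ci_high <- ci_o[2]
    row$repro_est <- est_r; row$repro_ci_low <- ci_r[1]; row$repro_ci_high <- ci_r[2]
    row$orig_p <- p_o; row$repro_p <- p_r
    row$orig_n_ref <- n_o[2]; row$repro_n_ref <- n_r[2]
  }
  row$orig_n_exp <- n_o[1]
  row$repro_n_exp <- n_r[1]
  extra <- list(...)
  for (nm in names(extra)) row[[nm]] <- extra[[nm]]
  row
}

make_pairs <- function(...) dplyr::bind_rows(...)

# Random valid comparative portfolio rows (deterministic given seed).
random_pairs <- function(n, seed = 42) {
  withr::with_seed(seed, {
    lo <- stats::rnorm(n, 0, 0.5)
    lr <- lo + stats::rnorm(n, 0, 0.2)
    se_o <- stats::runif(n, 0.05, 0.3)
    se_r <- stats::runif(n, 0.05, 0.3)
    z <- stats::qnorm(0.975)
    rows <- lapply(seq_len(n), function(i) {
      make_pair(sprintf("R%03d", i),
                est_o = exp(lo[i]), ci_o = exp(lo[i] + c(-1, 1) * z * se_o[i]),
                est_r = exp(lr[i]), ci_r = exp(lr[i] + c(-1, 1) * z * se_r[i]))
    })
    dplyr::bind_rows(rows)
  })
}

expect_close <- function(object, expected, tol = 1e-10) {
  expect_equal(object, expected, tolerance = tol)
}
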