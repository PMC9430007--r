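# Per-study concordance between the original and reproduced measure of
# association. All metrics operate on the natural-log scale; the null is
# fixed at 1.0 on the ratio scale (0 on the log scale).

Z975 <- function() qnorm(0.975)

es_point <- function(x) {
  p <- if (inherits(x, "effect_estimate")) x$point else x
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0)) {
    abort("Effect estimates must be positive (ratio scale).")
  }
  p
}

es_ci <- function(x) {
  if (!inherits(x, "effect_estimate")) {
    abort("A full `effect_estimate` with CI is required here.")
  }
  if (is.na(x$ci_low) || is.na(x$ci_high)) {
    abort("Confidence interval absent but required.")
  }
  c(x$ci_low, x$ci_high)
}

#' Relative magnitude of effect
#'
#' The ratio of the original to the reproduced effect estimate
#' (e.g. HR_original / HR_reproduction); 1.0 indicates perfect agreement.
#' Satisfies `relative_magnitude(a, b) * relative_magnitude(b, a) == 1`.
#'
#' @param original,reproduction Positive effect estimates, as bare numbers or
#'   [effect_estimate()] objects.
#' @return A positive real.
#' @export
#' @examples
#' relative_magnitude(1.2, 2.0) # 0.6
relative_magnitude <- function(original, reproduction) {
  es_point(original) / es_point(reproduction)
}

#' Absolute difference in log effect size
#'
#' `|log(ES_original) - log(ES_reproduction)|`, the primary per-study
#' irreproducibility distance. Symmetric in its arguments and a metric on
#' positive reals.
#'
#' @inheritParams relative_magnitude
#' @return A non-negative real.
#' @export
abs_log_difference <- function(original, reproduction) {
  abs(log(es_point(original)) - log(es_point(reproduction)))
}

#' Which estimate is closer to the null?
#'
#' Compares `|log ES|` of the two estimates against the null value 1.0.
#' Equality within `tol` on the absolute log scale is reported as a tie
#' (essentially impossible on real data; strict comparison otherwise).
#'
#' @inheritParams relative_magnitude
#' @param tol Tie tolerance on `|log ES|` (default 1e-12).
#' @return `"reproduction_closer"`, `"original_closer"`, or `"tie"`.
#' @export
closer_to_null <- function(original, reproduction, tol = 1e-12) {
  a <- abs(log(es_point(original)))
  b <- abs(log(es_point(reproduction)))
  if (abs(a - b) < tol) "tie" else if (b < a) "reproduction_closer" else "original_closer"
}

#' Are both estimates on the same side of the null?
#'
#' Without `require_ci`, checks that the two point estimates sit on the same
#' side of 1.0 (a point exactly at the null agrees with either side). With
#' `require_ci = TRUE`, additionally requires both 95% CIs to exclude 1.0 on
#' that same side.
#'
#' @inheritParams relative_magnitude
#' @param require_ci Also require both CIs to exclude the null on the same
#'   side; both CIs must then be present.
#' @return Logical flag.
#' @export
same_side_of_null <- function(original, reproduction, require_ci = FALSE) {
  lo <- log(es_point(original))
  lr <- log(es_point(reproduction))
  same_points <- lo * lr > 0 || lo == 0 || lr == 0
  if (!require_ci) return(same_points)
  ci_o <- log(es_ci(original))
  ci_r <- log(es_ci(reproduction))
  same_points &&
    ((ci_o[2] < 0 && ci_r[2] < 0) || (ci_o[1] > 0 && ci_r[1] > 0))
}

#' Do the 95% confidence intervals overlap?
#'
#' Closed-interval intersection: touching endpoints count as overlap
#' (conservative toward agreement).
#'
#' @inheritParams relative_magnitude
#' @return Logical flag.
#' @export
ci_overlap <- function(original, reproduction) {
  a <- es_ci(original)
  b <- es_ci(reproduction)
  max(a[1], b[1]) <= min(a[2], b[2])
}

#' Statistical-significance discordance
#'
#' TRUE when one study's p-value exceeds `alpha_loose` (failing to reject the
#' null at the conventional threshold) while the other's is at or below
#' `alpha_strict` (a stringent rejection), in either direction. Symmetric in
#' its two arguments.
#'
#' @param p_original,p_reproduction Two-sided p-values in `[0, 1]`.
#' @param alpha_loose,alpha_strict Thresholds (defaults 0.05 and 0.01).
#' @return Logical flag.
#' @export
significance_discordance <- function(p_original, p_reproduction,
                                     alpha_loose = 0.05, alpha_strict = 0.01) {
  ps <- c(p_original, p_reproduction)
  if (anyNA(ps) || any(ps < 0) || any(ps > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  (p_reproduction > alpha_loose && p_original <= alpha_strict) ||
    (p_original > alpha_loose && p_reproduction <= alpha_strict)
}

#' Two-sided p-value back-calculated from a ratio-scale CI
#'
#' Normal approximation on the log scale:
#' `se = (log U - log L) / (2 * z_0.975)`, `z = log(point) / se`,
#' `p = 2 * (1 - Phi(|z|))`. Used when a source row does not print a p-value;
#' rows using it carry a provenance flag in [concordance_table()].
#'
#' @param estimate An [effect_estimate()] with a non-degenerate CI.
#' @return A p-value in `[0, 1]`.
#' @export
p_from_estimate <- function(estimate) {
  ci <- es_ci(estimate)
  if (ci[2] <= ci[1]) abort("Degenerate CI (upper <= lower).")
  se <- (log(ci[2]) - log(ci[1])) / (2 * Z975())
  2 * pnorm(-abs(log(estimate$point) / se))
}

# log-scale standard error from a ratio-scale CI; vectorised.
se_from_ci <- function(ci_low, ci_high) {
  (log(ci_high) - log(ci_low)) / (2 * Z975())
}

#' Per-study concordance table
#'
#' Computes every per-study effect-concordance metric for the comparative
#' studies of a validated portfolio. Descriptive studies carry no measure of
#' association and are skipped with a message. Rows whose metrics cannot be
#' computed are reported in an `errors` attribute rather than aborting the
#' whole table.
#'
#' The `within_01` / `within_02` flags use inclusive thresholds
#' `abs_log_diff <= 0.1` and `<= 0.2`. When a study does not print a p-value
#' it is back-calculated from the CI via [p_from_estimate()] and flagged in
#' `p_orig_source` / `p_repro_source` (`"reported"` vs `"from_ci"`).
#'
#' @param pairs A validated studies tibble ([read_study_pairs()] or
#'   [generate_portfolio()]).
#' @param config Threshold configuration from [concordance_config()].
#' @return A tibble with one row per comparative study: `rel_magnitude`,
#'   `signed_log_diff`, `abs_log_diff`, `within_01`, `within_02`,
#'   `repro_closer_to_null`, `same_side_of_null`, `both_est_and_ci_same_side`,
#'   `ci_overlap`, `signif_discordant`, `p_diff`, log-scale estimates and
#'   standard errors, and the subgroup attributes carried through.
#' @export
concordance_table <- function(pairs, config = concordance_config()) {
  pairs <- as_tibble(pairs)
  n_desc <- sum(pairs$design == "descriptive")
  if (n_desc > 0) {
    inform(sprintf("Skipping %d descriptive studies (no measure of association).", n_desc))
  }
  comp <- pairs[pairs$design == "comparative", , drop = FALSE]

  rows <- vector("list", nrow(comp))
  errors <- list()
  for (i in seq_len(nrow(comp))) {
    row <- as.list(comp[i, ])
    res <- tryCatch(concordance_row(row, config), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[length(errors) + 1L]] <-
        tibble(study_id = row$study_id, reason = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  out <- bind_rows(rows)
  attr_cols <- c("funding_source", "data_source", "publication_year",
                 "journal_impact_band", "author_responsive", "same_group")
  keep <- intersect(attr_cols, names(comp))
  if (nrow(out) > 0 && length(keep) > 0) {
    out <- left_join(out, comp[c("study_id", keep)], by = "study_id")
  }
  structure(out, errors = bind_rows(errors))
}

concordance_row <- function(row, config) {
  eo <- effect_estimate(row$orig_est, row$orig_ci_low, row$orig_ci_high,
                        row$orig_p %||% NA_real_)
  er <- effect_estimate(row$repro_est, row$repro_ci_low, row$repro_ci_high,
                        row$repro_p %||% NA_real_)
  has_ci <- !is.na(eo$ci_low) && !is.na(er$ci_low)

  p_orig <- eo$p_value
  p_orig_source <- "reported"
  if (is.na(p_orig) && !is.na(eo$ci_low)) {
    p_orig <- p_from_estimate(eo)
    p_orig_source <- "from_ci"
  }
  p_repro <- er$p_value
  p_repro_source <- "reported"
  if (is.na(p_repro) && !is.na(er$ci_low)) {
    p_repro <- p_from_estimate(er)
    p_repro_source <- "from_ci"
  }

  sld <- log(eo$point) - log(er$point)
  ald <- abs(sld)
  tibble(
    study_id = row$study_id,
    measure = row$measure,
    log_es_orig = log(eo$point),
    log_es_repro = log(er$point),
    se_orig = if (!is.na(eo$ci_low)) se_from_ci(eo$ci_low, eo$ci_high) else NA_real_,
    se_repro = if (!is.na(er$ci_low)) se_from_ci(er$ci_low, er$ci_high) else NA_real_,
    rel_magnitude = relative_magnitude(eo, er),
    signed_log_diff = sld,
    abs_log_diff = ald,
    within_01 = ald <= config$log_diff_thresholds[1],
    within_02 = ald <= config$log_diff_thresholds[2],
    repro_closer_to_null = closer_to_null(eo, er, tol = config$tie_tol),
    same_side_of_null = same_side_of_null(eo, er, require_ci = FALSE),
    both_est_and_ci_same_side =
      if (has_ci) same_side_of_null(eo, er, require_ci = TRUE) else NA,
    ci_overlap = if (has_ci) ci_overlap(eo, er) else NA,
    signif_discordant = if (!is.na(p_orig) && !is.na(p_repro)) {
      significance_discordance(p_orig, p_repro,
                               config$alpha_loose, config$alpha_strict)
    } else NA,
    p_orig = p_orig,
    p_repro = p_repro,
    p_diff = p_orig - p_repro,
    p_orig_source = p_orig_source,
    p_repro_source = p_repro_source
  )
}

#' Threshold configuration for the concordance metrics
#'
#' @param log_diff_thresholds Inclusive `abs_log_diff` thresholds for the
#'   `within_01` / `within_02` flags (default `c(0.1, 0.2)`).
#' @param alpha_loose,alpha_strict Significance-discordance thresholds
#'   (defaults 0.05 and 0.01).
#' @param tie_tol Closer-to-null tie tolerance (default 1e-12).
#' @param large_diff_pct Strict threshold (percentage points, or events per
#'   100 person-years for rates) above which a cohort difference is flagged
#'   large (default 10; `|diff| > 10`, a boundary value is not flagged).
#' @param size_extreme_bounds Relative sample-size bounds beyond which the
#'   ratio is flagged extreme (default `c(0.5, 2)`, strict inequalities).
#' @param ivw_weighting `"pair"` (default, weight `1/(se_o^2 + se_r^2)`) or
#'   `"original"` (weight `1/se_o^2`) for the IVW statistics.
#' @param partially_counts_as_reported Whether `partially_reported` counts
#'   toward the per-item reporting proportion (default FALSE, conservative).
#' @return A named list of class `concordance_config`.
#' @export
concordance_config <- function(log_diff_thresholds = c(0.1, 0.2),
                               alpha_loose = 0.05, alpha_strict = 0.01,
                               tie_tol = 1e-12,
                               large_diff_pct = 10,
                               size_extreme_bounds = c(0.5, 2),
                               ivw_weighting = c("pair", "original"),
                               partially_counts_as_reported = FALSE) {
  structure(
    list(
      log_diff_thresholds = log_diff_thresholds,
      alpha_loose = alpha_loose, alpha_strict = alpha_strict,
      tie_tol = tie_tol, large_diff_pct = large_diff_pct,
      size_extreme_bounds = size_extreme_bounds,
      ivw_weighting = match.arg(ivw_weighting),
      partially_counts_as_reported = partially_counts_as_reported
    ),
    class = "concordance_config"
  )
}
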