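# Portfolio-level agreement statistics across reproduced studies:
# unweighted and inverse-variance-weighted correlations of log effects,
# one-way intraclass correlation, Bland-Altman limits of agreement, outlier
# ranking, and a subgroup variance-in-means exploration.

#' Inverse-variance weights from 95% confidence intervals
#'
#' `w_i = 1 / se_i^2` with `se_i = (log U_i - log L_i) / (2 * z_0.975)`.
#' Weights are not normalised; normalisation is the consumer's choice.
#'
#' @param estimates A data frame with columns `ci_low` and `ci_high`, or a
#'   list of [effect_estimate()] objects.
#' @return A vector of positive weights.
#' @export
ivw_weights <- function(estimates) {
  if (is.data.frame(estimates)) {
    lo <- estimates$ci_low
    hi <- estimates$ci_high
  } else {
    lo <- vapply(estimates, function(e) es_ci(e)[1], numeric(1))
    hi <- vapply(estimates, function(e) es_ci(e)[2], numeric(1))
  }
  if (anyNA(lo) || anyNA(hi)) abort("All confidence intervals must be present.")
  if (any(hi <= lo)) abort("Degenerate CI (upper <= lower).")
  1 / se_from_ci(lo, hi)^2
}

check_xyw <- function(x, y, w) {
  if (length(x) != length(y) || length(x) != length(w)) {
    abort("x, y, and w must have equal length.")
  }
  if (length(x) < 3) abort("At least 3 observations are required.")
  if (any(w <= 0) || anyNA(w)) abort("Weights must be positive.")
  if (anyNA(x) || anyNA(y)) abort("x and y must be complete.")
}

#' Weighted Pearson correlation
#'
#' `r_w = sum(w (x - xbar_w)(y - ybar_w)) /
#'   sqrt(sum(w (x - xbar_w)^2) * sum(w (y - ybar_w)^2))` with weighted means
#' `xbar_w`, `ybar_w`. Equal weights reduce to the unweighted Pearson
#' correlation.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param w Positive weights.
#' @return A correlation in `[-1, 1]`.
#' @export
weighted_pearson <- function(x, y, w) {
  check_xyw(x, y, w)
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xm)^2)
  syy <- sum(w * (y - ym)^2)
  if (sxx == 0 || syy == 0) abort("Correlation undefined: zero variance.")
  sum(w * (x - xm) * (y - ym)) / sqrt(sxx * syy)
}

#' Weighted Spearman rank correlation
#'
#' [weighted_pearson()] applied to mid-ranks (ties receive average ranks).
#'
#' @inheritParams weighted_pearson
#' @return A correlation in `[-1, 1]`.
#' @export
weighted_spearman <- function(x, y, w) {
  check_xyw(x, y, w)
  weighted_pearson(rank(x, ties.method = "average"),
                   rank(y, ties.method = "average"), w)
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' Treats the original and reproduced log effect estimates as two unordered
#' measurements of each study. From the one-way ANOVA with n subjects and
#' k = 2 measurements each: `ICC = (MSB - MSW) / (MSB + (k - 1) MSW)`. The
#' confidence interval uses `F = MSB / MSW` with
#' `F_L = F / qf(1 - alpha/2, n - 1, n(k - 1))` and
#' `F_U = F * qf(1 - alpha/2, n(k - 1), n - 1)`, giving bounds
#' `(F_L - 1) / (F_L + k - 1)` and `(F_U - 1) / (F_U + k - 1)`.
#'
#' @param pairs A two-column matrix or data frame (log-scale values), one row
#'   per subject.
#' @param alpha CI level complement (default 0.05 for a 95% interval).
#' @return A list with `icc`, `ci` (length-2 vector), `msb`, `msw`, `n`.
#' @export
icc_oneway <- function(pairs, alpha = 0.05) {
  m <- as.matrix(pairs)
  if (ncol(m) != 2) abort("`pairs` must have exactly two columns.")
  if (anyNA(m)) m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3) abort("At least 3 complete pairs are required.")
  k <- 2
  row_means <- rowMeans(m)
  grand <- mean(m)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msb == 0 && msw == 0) abort("ICC undefined: all values identical.")
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  if (msw == 0) {
    ci <- c(1, 1)
  } else {
    f <- msb / msw
    fl <- f / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f * qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci = ci, msb = msb, msw = msw, n = n)
}

#' Bland-Altman limits of agreement on the log-effect scale
#'
#' Per study, plots `diff_i = log ES_original - log ES_reproduction` against
#' `mean_i = (log ES_original + log ES_reproduction) / 2`. Agreement limits
#' are drawn at `mean(diff) +/- 2 * sd(diff)` (sample SD, n-1 denominator;
#' the multiplier is exactly 2, not 1.96).
#'
#' @param log_orig,log_repro Log-scale effect estimates (equal length >= 2).
#' @param study_id Optional study labels.
#' @return A list of class `bland_altman`: `data` (tibble of `study_id`,
#'   `pair_mean`, `pair_diff`), `mean_diff`, `sd_diff`, `lower_limit`,
#'   `upper_limit`, and `outside_limits` (study ids beyond the limits).
#' @export
bland_altman <- function(log_orig, log_repro, study_id = NULL) {
  if (length(log_orig) != length(log_repro)) abort("Inputs must have equal length.")
  n <- length(log_orig)
  if (n < 2) abort("At least 2 pairs are required.")
  if (is.null(study_id)) study_id <- as.character(seq_len(n))
  d <- log_orig - log_repro
  m <- (log_orig + log_repro) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  lower <- mean_diff - 2 * sd_diff
  upper <- mean_diff + 2 * sd_diff
  structure(
    list(
      data = tibble(study_id = study_id, pair_mean = m, pair_diff = d),
      mean_diff = mean_diff, sd_diff = sd_diff,
      lower_limit = lower, upper_limit = upper,
      outside_limits = study_id[d < lower | d > upper]
    ),
    class = "bland_altman"
  )
}

#' Most extreme outliers by absolute log-difference
#'
#' The `k` studies with the largest `|log ES_original - log ES_reproduction|`,
#' in descending order; ties are broken by lexicographic study id.
#'
#' @param rows A concordance table from [concordance_table()].
#' @param k Number of outliers to return (default 10, `k <= nrow(rows)`).
#' @return A character vector of study ids.
#' @export
top_outliers <- function(rows, k = 10) {
  if (k > nrow(rows)) abort("`k` exceeds the number of studies.")
  ord <- order(-rows$abs_log_diff, rows$study_id)
  rows$study_id[ord][seq_len(k)]
}

prop_of <- function(x) {
  # proportion over the non-missing denominator, with the denominator kept
  n <- sum(!is.na(x))
  list(value = if (n > 0) sum(x, na.rm = TRUE) / n else NA_real_, n = n)
}

#' Portfolio-level agreement summary
#'
#' Aggregates a concordance table into the portfolio statistics: unweighted
#' and inverse-variance-weighted Pearson and Spearman correlations of the log
#' effects, ICC(1) with 95% CI, the median/IQR/range of the relative
#' magnitude, agreement proportions, the p-value difference distribution
#' among same-side studies, and the mean absolute log-difference by side
#' agreement. Quantiles use linear interpolation (type 7). Proportions are
#' computed over non-missing denominators, which are reported alongside.
#'
#' The IVW weight per study pair is `1 / (se_o^2 + se_r^2)` by default (the
#' pair-level precision); set `ivw_weighting = "original"` in the config for
#' `1 / se_o^2`.
#'
#' @param rows A concordance table from [concordance_table()].
#' @param config A [concordance_config()].
#' @return A list of class `agreement_summary` (JSON-serialisable).
#' @export
summarize_agreement <- function(rows, config = concordance_config()) {
  if (nrow(rows) < 3) abort("At least 3 comparative studies are required.")
  x <- rows$log_es_orig
  y <- rows$log_es_repro

  has_ci <- !is.na(rows$se_orig) & !is.na(rows$se_repro)
  w <- if (config$ivw_weighting == "pair") {
    1 / (rows$se_orig^2 + rows$se_repro^2)
  } else {
    1 / rows$se_orig^2
  }
  ivw_ok <- sum(has_ci) >= 3

  q <- function(v, p) unname(quantile(v, p, type = 7, na.rm = TRUE))
  same <- rows$same_side_of_null
  p_diff_ss <- rows$p_diff[same %in% TRUE]
  p_diff_ss <- p_diff_ss[!is.na(p_diff_ss)]

  icc_fit <- icc_oneway(cbind(x, y))

  props <- list(
    prop_within_01 = prop_of(rows$within_01),
    prop_within_02 = prop_of(rows$within_02),
    prop_repro_closer_null = prop_of(rows$repro_closer_to_null == "reproduction_closer"),
    prop_same_side = prop_of(rows$same_side_of_null),
    prop_same_side_with_ci = prop_of(rows$both_est_and_ci_same_side),
    prop_ci_overlap = prop_of(rows$ci_overlap),
    prop_signif_discordant = prop_of(rows$signif_discordant)
  )

  out <- c(
    list(
      n_studies = nrow(rows),
      pearson_unweighted = weighted_pearson(x, y, rep(1, length(x))),
      pearson_ivw = if (ivw_ok) weighted_pearson(x[has_ci], y[has_ci], w[has_ci]) else NA_real_,
      spearman_unweighted = weighted_spearman(x, y, rep(1, length(x))),
      spearman_ivw = if (ivw_ok) weighted_spearman(x[has_ci], y[has_ci], w[has_ci]) else NA_real_,
      icc = icc_fit$icc,
      icc_ci = icc_fit$ci,
      median_rel_magnitude = q(rows$rel_magnitude, 0.5),
      iqr_rel_magnitude = q(rows$rel_magnitude, c(0.25, 0.75)),
      range_rel_magnitude = range(rows$rel_magnitude)
    ),
    lapply(props, `[[`, "value"),
    list(
      median_p_diff_same_side = if (length(p_diff_ss)) q(p_diff_ss, 0.5) else NA_real_,
      iqr_p_diff_same_side = if (length(p_diff_ss)) q(p_diff_ss, c(0.25, 0.75)) else c(NA_real_, NA_real_),
      mean_abs_log_diff_same_side = mean(rows$abs_log_diff[same %in% TRUE]),
      mean_abs_log_diff_opposite_side =
        if (any(same %in% FALSE)) mean(rows$abs_log_diff[same %in% FALSE]) else NA_real_,
      denominators = lapply(props, `[[`, "n"),
      ivw_weighting = config$ivw_weighting
    )
  )
  structure(out, class = "agreement_summary")
}

#' Subgroup variation in mean absolute log-difference
#'
#' Explores whether average irreproducibility differs across levels of a
#' study attribute (funding source, data source, publication year, ...) via
#' a classical one-way ANOVA on `abs_log_diff`, with no multiple-testing
#' adjustment. When all values are identical across groups the F statistic is
#' degenerate and p is reported as 1 with a `degenerate` flag.
#'
#' @param rows A concordance table carrying the attribute column.
#' @param grouping Name of the attribute column to group by.
#' @return A tibble of per-group `n`, `mean_abs_log_diff`, `sd`, with the
#'   ANOVA `statistic` (F), `df`, and `p_value` as attributes (`anova`).
#' @export
subgroup_variation <- function(rows, grouping) {
  if (!grouping %in% names(rows)) {
    abort(sprintf("Column `%s` not found in the concordance table.", grouping))
  }
  g <- factor(rows[[grouping]])
  v <- rows$abs_log_diff
  keep <- !is.na(g) & !is.na(v)
  g <- droplevels(g[keep])
  v <- v[keep]
  sizes <- table(g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need at least 2 groups with at least 2 members each.")
  }
  per_group <- tibble(
    group = names(sizes),
    n = as.integer(sizes),
    mean_abs_log_diff = as.numeric(tapply(v, g, mean)),
    sd = as.numeric(tapply(v, g, sd))
  )
  k <- length(sizes)
  n <- length(v)
  grand <- mean(v)
  ssb <- sum(sizes * (tapply(v, g, mean) - grand)^2)
  ssw <- sum((v - ave(v, g))^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  degenerate <- msw == 0
  f_stat <- if (degenerate) NA_real_ else msb / msw
  p <- if (degenerate) 1 else stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  structure(per_group,
            anova = list(statistic = f_stat, df = c(k - 1, n - k),
                         p_value = p, degenerate = degenerate))
}
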