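# Portfolio-level agreement statistics.

test_that("ivw weights are inverse squared log-scale standard errors", {
  # CI spanning exactly 2 * z * 0.1 on the log scale -> se 0.1 -> weight 100
  ci <- tibble::tibble(ci_low = 1, ci_high = exp(2 * qnorm(0.975) * 0.1))
  expect_close(ivw_weights(ci), 100, 1e-9)
  # identical log-widths give equal weights
  many <- tibble::tibble(ci_low = c(0.5, 1, 2), ci_high = c(0.5, 1, 2) * exp(0.4))
  w <- ivw_weights(many)
  expect_true(all(abs(w - w[1]) < 1e-10))
  expect_error(ivw_weights(tibble::tibble(ci_low = 1, ci_high = 1)), "Degenerate")
})

test_that("weighted Pearson reduces to cor() under equal weights", {
  withr::with_seed(17, {
    for (i in 1:20) {
      x <- rnorm(10)
      y <- rnorm(10)
      expect_close(weighted_pearson(x, y, rep(2.7, 10)), cor(x, y), 1e-12)
    }
  })
})

test_that("weighted Pearson is exact under perfect linearity and matches a
           direct-summation oracle on unequal weights", {
  x <- c(0.2, 1.4, -0.6, 2.2, 0.9)
  w <- c(1, 5, 2, 0.5, 3)
  expect_close(weighted_pearson(x, 2 * x + 1, w), 1.0, 1e-12)

  y <- c(0.4, 1.1, -0.2, 1.4, 1.3)
  # oracle: expand weights into replicated observations (integer weights)
  wi <- c(1, 5, 2, 4, 3)
  xr <- rep(x, wi)
  yr <- rep(y, wi)
  expect_close(weighted_pearson(x, y, wi), cor(xr, yr), 1e-12)
  expect_error(weighted_pearson(rep(1, 5), y, wi), "zero variance")
})

test_that("weighted Spearman works through mid-ranks", {
  x <- c(0.1, 0.7, 1.4, 2.2, 3.0)
  expect_close(weighted_spearman(x, exp(x), rep(1, 5)), 1.0, 1e-12)
  expect_close(weighted_spearman(x, -x^3, rep(1, 5)), -1.0, 1e-12)
  # ties: mid-ranks enumerated by hand
  xt <- c(1, 2, 2, 3)
  yt <- c(4, 5, 6, 6)
  w <- c(1, 2, 1, 1)
  rx <- c(1, 2.5, 2.5, 4)
  ry <- c(1, 2, 3.5, 3.5)
  expect_close(weighted_spearman(xt, yt, w), weighted_pearson(rx, ry, w), 1e-12)
  # equal weights agree with stats::cor(method = "spearman")
  withr::with_seed(23, {
    x <- sample(1:8, 10, replace = TRUE)
    y <- sample(1:8, 10, replace = TRUE)
    expect_close(weighted_spearman(x, y, rep(1, 10)),
                 cor(x, y, method = "spearman"), 1e-12)
  })
})

test_that("ICC(1) matches an ANOVA-by-enumeration oracle on a 6-pair fixture", {
  m <- cbind(c(0.2, -0.4, 1.1, 0.6, -0.9, 0.3),
             c(0.25, -0.5, 0.9, 0.7, -0.8, 0.1))
  fit <- icc_oneway(m)
  # oracle: sums of squares by direct enumeration
  n <- nrow(m); k <- 2
  grand <- mean(m)
  ssb <- 0; ssw <- 0
  for (i in seq_len(n)) {
    mi <- mean(m[i, ])
    ssb <- ssb + k * (mi - grand)^2
    for (j in 1:k) ssw <- ssw + (m[i, j] - mi)^2
  }
  msb <- ssb / (n - 1); msw <- ssw / (n * (k - 1))
  expect_close(fit$icc, (msb - msw) / (msb + msw), 1e-12)
  # cross-check mean squares against stats::aov
  long <- data.frame(y = as.vector(t(m)), subj = factor(rep(1:n, each = k)))
  ms <- summary(stats::aov(y ~ subj, data = long))[[1]][["Mean Sq"]]
  expect_close(fit$msb, ms[1], 1e-12)
  expect_close(fit$msw, ms[2], 1e-12)
  expect_lt(fit$ci[1], fit$icc)
  expect_gt(fit$ci[2], fit$icc)
})

test_that("ICC hits its boundary cases", {
  # duplicated measurements with between-subject spread: ICC exactly 1
  x <- c(0.3, -0.2, 0.8, 1.4)
  fit <- icc_oneway(cbind(x, x))
  expect_close(fit$icc, 1)
  expect_equal(fit$ci, c(1, 1))
  expect_error(icc_oneway(cbind(rep(1, 5), rep(1, 5))), "identical")
  # independent coordinates: ICC near zero (Monte Carlo tolerance ~ 3/sqrt(n))
  withr::with_seed(41, {
    fit0 <- icc_oneway(cbind(rnorm(2000), rnorm(2000)))
    expect_lt(abs(fit0$icc), 3 / sqrt(2000))
  })
})

test_that("ICC approaches 1 as paired noise vanishes and decreases in noise", {
  withr::with_seed(43, {
    x <- rnorm(300, 0, 1)
    iccs <- vapply(c(1, 0.5, 0.1, 0.01), function(s) {
      icc_oneway(cbind(x + rnorm(300, 0, s), x + rnorm(300, 0, s)))$icc
    }, numeric(1))
    expect_true(all(diff(iccs) > 0))
    expect_gt(iccs[4], 0.999)
  })
})

test_that("Bland-Altman limits are mean +/- 2 sample SDs", {
  # all-zero differences collapse the limits
  ba0 <- bland_altman(c(0.1, 0.5, -0.2), c(0.1, 0.5, -0.2))
  expect_close(ba0$mean_diff, 0)
  expect_close(ba0$lower_limit, 0)
  expect_length(ba0$outside_limits, 0)

  # diffs {-1, 1}: mean 0, sd sqrt(2), limits +/- 2 sqrt(2)
  ba <- bland_altman(c(-0.5, 0.5), c(0.5, -0.5))
  expect_close(ba$mean_diff, 0)
  expect_close(ba$sd_diff, sqrt(2))
  expect_close(ba$upper_limit, 2 * sqrt(2))
  expect_close(ba$lower_limit, -2 * sqrt(2))

  # translation property: shifting log ES_o by c shifts the mean only
  withr::with_seed(3, {
    lo <- rnorm(20); lr <- rnorm(20)
    b1 <- bland_altman(lo, lr)
    b2 <- bland_altman(lo + 0.7, lr)
    expect_close(b2$mean_diff, b1$mean_diff + 0.7)
    expect_close(b2$sd_diff, b1$sd_diff)
  })
  expect_error(bland_altman(1, numeric(0)), "equal length")
})

test_that("Bland-Altman limits cover roughly 95% of normal differences", {
  withr::with_seed(47, {
    lo <- rnorm(2000); lr <- lo + rnorm(2000, 0, 0.3)
    ba <- bland_altman(lo, lr)
    frac_out <- length(ba$outside_limits) / 2000
    # P(|Z| > 2) = 4.55%; binomial 3-sigma band around it
    expect_lt(abs(frac_out - 0.0455), 3 * sqrt(0.0455 * 0.9545 / 2000))
  })
})

test_that("top_outliers ranks by absolute log-difference with lexicographic ties", {
  rows <- tibble::tibble(
    study_id = c("B", "A", "C", "D"),
    abs_log_diff = c(0.5, 0.5, 0.9, 0.1)
  )
  expect_equal(top_outliers(rows, 4), c("C", "A", "B", "D"))
  expect_equal(top_outliers(rows, 1), "C")
  expect_equal(top_outliers(rows, 2), c("C", "A"))  # tie at rank 2 -> "A"
  expect_error(top_outliers(rows, 5), "exceeds")
})

test_that("summarize_agreement equals an independent per-field recomputation", {
  pairs <- random_pairs(10, seed = 77)
  rows <- concordance_table(pairs)
  s <- summarize_agreement(rows)

  lo <- rows$log_es_orig; lr <- rows$log_es_repro
  expect_close(s$pearson_unweighted, cor(lo, lr), 1e-12)
  expect_close(s$spearman_unweighted, cor(lo, lr, method = "spearman"), 1e-10)
  w <- 1 / (rows$se_orig^2 + rows$se_repro^2)
  expect_close(s$pearson_ivw, weighted_pearson(lo, lr, w), 1e-12)
  expect_close(s$icc, icc_oneway(cbind(lo, lr))$icc, 1e-12)
  expect_close(s$median_rel_magnitude,
               unname(quantile(rows$rel_magnitude, 0.5, type = 7)), 1e-12)
  expect_close(s$iqr_rel_magnitude,
               unname(quantile(rows$rel_magnitude, c(0.25, 0.75), type = 7)), 1e-12)
  expect_close(s$prop_within_01, mean(rows$abs_log_diff <= 0.1), 1e-12)
  expect_close(s$prop_within_02, mean(rows$abs_log_diff <= 0.2), 1e-12)
  expect_close(s$prop_repro_closer_null, mean(abs(lr) < abs(lo)), 1e-12)
  expect_close(s$prop_same_side, mean(lo * lr > 0), 1e-12)
  expect_close(s$prop_ci_overlap,
               mean(pmax(pairs$orig_ci_low, pairs$repro_ci_low) <=
                      pmin(pairs$orig_ci_high, pairs$repro_ci_high)), 1e-12)
  same <- lo * lr > 0
  expect_close(s$mean_abs_log_diff_same_side, mean(rows$abs_log_diff[same]), 1e-12)
  expect_equal(s$denominators$prop_within_01, 10)
})

test_that("summary is invariant to row permutation and perfect under identity", {
  pairs <- random_pairs(12, seed = 99)
  rows <- concordance_table(pairs)
  s1 <- summarize_agreement(rows)
  s2 <- summarize_agreement(rows[sample(nrow(rows)), ])
  nm <- setdiff(names(s1), "denominators")
  expect_equal(s1[nm], s2[nm])

  ident <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_pair(sprintf("I%d", i), est_o = 1 + i / 4, est_r = 1 + i / 4,
              p_o = 0.01, p_r = 0.01)
  }))
  si <- summarize_agreement(concordance_table(ident))
  expect_close(si$median_rel_magnitude, 1)
  expect_close(si$prop_within_01, 1)
  expect_close(si$prop_same_side, 1)
  expect_close(si$prop_ci_overlap, 1)
  expect_close(si$prop_signif_discordant, 0)
  expect_close(si$icc, 1)
})

test_that("subgroup variation reproduces the two-sample t identity and
           handles degenerate groups", {
  rows <- tibble::tibble(
    study_id = sprintf("S%d", 1:10),
    abs_log_diff = c(0.1, 0.3, 0.2, 0.25, 0.15, 0.4, 0.5, 0.45, 0.35, 0.6),
    grp = rep(c("a", "b"), each = 5)
  )
  res <- subgroup_variation(rows, "grp")
  aov_res <- attr(res, "anova")
  tt <- stats::t.test(abs_log_diff ~ grp, data = rows, var.equal = TRUE)
  expect_close(aov_res$statistic, unname(tt$statistic)^2, 1e-10)
  expect_close(aov_res$p_value, tt$p.value, 1e-10)

  flat <- tibble::tibble(study_id = sprintf("S%d", 1:6),
                         abs_log_diff = rep(0.2, 6),
                         grp = rep(c("a", "b"), 3))
  res0 <- subgroup_variation(flat, "grp")
  a0 <- attr(res0, "anova")
  expect_true(a0$degenerate)
  expect_equal(a0$p_value, 1)

  expect_error(subgroup_variation(rows[1:2, ], "grp"), "at least 2")
})

test_that("null-simulation ANOVA p-values are uniform", {
  withr::with_seed(53, {
    ps <- replicate(200, {
      rows <- tibble::tibble(
        study_id = as.character(1:30),
        abs_log_diff = abs(rnorm(30, 0.2, 0.1)),
        grp = rep(c("a", "b", "c"), each = 10)
      )
      attr(subgroup_variation(rows, "grp"), "anova")$p_value
    })
    expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  })
})
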