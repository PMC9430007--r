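# Synthetic paired-study portfolios with known truth.
#
# Generative model (per comparative study i, all on the natural-log scale):
#   theta_i ~ Normal(mu_theta, tau^2)                  true log effect
#   sigma_i = sqrt(1/e1_i + 1/e0_i)                    sampling SE from the
#                                                      original arm event
#                                                      counts (log-rate-ratio
#                                                      approximation)
#   eps_shared_i ~ Normal(0, f * sigma_i^2)            error common to both
#                                                      analyses (same source
#                                                      data), f = shared
#                                                      error fraction
#   eps_o_i, eps_r_i ~ Normal(0, (1 - f) * sigma_i^2)  independent halves
#   delta_i ~ (1 - pi_big) Normal(0, omega_small^2)    implementation
#             + pi_big   Normal(0, omega_big^2)        discrepancy mixture
#   log ES_o = theta + eps_shared + eps_o
#   log ES_r = theta + delta + eps_shared + eps_r
# Reproduction cohort sizes are N_o * exp(Normal(0, size_ratio_logsd^2));
# with probability dataversion_shift_prob a reproduction's outcome rates are
# shifted upward by Uniform(rate_shift_band) events per 100 person-years
# (emulating retroactive source-data updates); covariate prevalences are
# perturbed by a small Gaussian shift plus a rare large shift (emulating
# mis-specified covariate algorithms); p-values are masked (absent) at
# random to emulate reporting omission.
#
# Everything is drawn from one seeded generator in a fixed stream order
# (comparative block, descriptive block, covariates, checklist, attributes),
# so identical seeds give identical portfolios.

#' Configuration of the synthetic portfolio generator
#'
#' Defaults are the "paper-like" preset: 118 comparative and 32 descriptive
#' studies, a true-effect spread and noise mix chosen so that downstream
#' summaries land in realistic neighbourhoods (median relative magnitude
#' near 1, CI overlap well above 50%). All modelling choices live here, not
#' in code constants.
#'
#' @param n_comparative,n_descriptive Portfolio composition.
#' @param mu_theta,tau Mean and SD of the true log-effect distribution.
#' @param event_count_range Integer range of outcome events per arm in the
#'   original study (drives the sampling SE).
#' @param shared_error_fraction Fraction `f` of sampling variance common to
#'   both analyses (both teams analyse the same source data).
#' @param discrepancy_mix List `pi_big`, `omega_small`, `omega_big`: the
#'   two-component normal mixture of the implementation discrepancy
#'   `delta_i` (`omega_small <= omega_big`).
#' @param size_ratio_logsd SD of the log reproduction/original size ratio.
#' @param dataversion_shift_prob Probability that a study's reproduction hit
#'   a retroactive data-version update.
#' @param rate_shift_band Uniform band (per 100 person-years) of the rate
#'   shift in a data-version event.
#' @param covariate_shift List `sd_small`, `prob_large`, `magnitude_large`
#'   (percentage points) for the prevalence perturbation mixture.
#' @param n_covariates Baseline covariates generated per study.
#' @param p_report_prob Probability that a study prints its p-values
#'   (reporting-omission mask).
#' @param measure_probs Sampling probabilities of HR / RR / OR labels.
#' @param assumption_prob Named per-category assumption probabilities for
#'   comparative and descriptive studies (checklist generation).
#' @param item_response_probs Probabilities of reported / partially_reported
#'   / not_reported for applicable checklist items.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_comparative = 118, n_descriptive = 32,
                       mu_theta = 0, tau = 0.5,
                       event_count_range = c(20L, 500L),
                       shared_error_fraction = 0.5,
                       discrepancy_mix = list(pi_big = 0.1, omega_small = 0.1,
                                              omega_big = 0.5),
                       size_ratio_logsd = 0.45,
                       dataversion_shift_prob = 0.05,
                       rate_shift_band = c(13, 16),
                       covariate_shift = list(sd_small = 2, prob_large = 0.17,
                                              magnitude_large = 20),
                       n_covariates = 10,
                       p_report_prob = 0.6,
                       measure_probs = c(HR = 0.7, RR = 0.15, OR = 0.15),
                       assumption_prob = c(comparative = 0.65, descriptive = 0.6),
                       item_response_probs = c(reported = 0.55,
                                               partially_reported = 0.15,
                                               not_reported = 0.30),
                       seed = NULL) {
  cfg <- list(
    n_comparative = n_comparative, n_descriptive = n_descriptive,
    mu_theta = mu_theta, tau = tau,
    event_count_range = as.integer(event_count_range),
    shared_error_fraction = shared_error_fraction,
    discrepancy_mix = discrepancy_mix,
    size_ratio_logsd = size_ratio_logsd,
    dataversion_shift_prob = dataversion_shift_prob,
    rate_shift_band = rate_shift_band,
    covariate_shift = covariate_shift,
    n_covariates = n_covariates,
    p_report_prob = p_report_prob,
    measure_probs = measure_probs,
    assumption_prob = assumption_prob,
    item_response_probs = item_response_probs,
    seed = seed
  )
  probs <- c(cfg$shared_error_fraction, cfg$dataversion_shift_prob,
             cfg$discrepancy_mix$pi_big, cfg$covariate_shift$prob_large,
             cfg$p_report_prob)
  if (any(probs < 0) || any(probs > 1)) abort("Probabilities must lie in [0, 1].")
  sds <- c(cfg$tau, cfg$discrepancy_mix$omega_small, cfg$discrepancy_mix$omega_big,
           cfg$size_ratio_logsd, cfg$covariate_shift$sd_small)
  if (any(sds < 0)) abort("Standard deviations must be non-negative.")
  if (cfg$discrepancy_mix$omega_small > cfg$discrepancy_mix$omega_big) {
    abort("omega_small must not exceed omega_big.")
  }
  if (cfg$event_count_range[1] < 1 ||
      cfg$event_count_range[2] < cfg$event_count_range[1]) {
    abort("event_count_range must be an increasing range of positive counts.")
  }
  if (cfg$n_comparative < 0 || cfg$n_descriptive < 0) {
    abort("Portfolio sizes must be non-negative.")
  }
  structure(cfg, class = "sim_config")
}

# one exposure group's observed occurrence block: counts, risk, rate
gen_arm_block <- function(events, n, followup_years) {
  py <- n * followup_years
  tibble(
    n = n, events = events,
    risk = 100 * events / n,
    rate = 100 * events / py,
    py = py
  )
}

# reproduction counts: the re-extracted cohort observes Poisson events at
# the original rate (plus any data-version shift); risk/rate are recomputed
# from the realised counts so the tables are internally consistent
repro_arm_block <- function(orig_rate, n_r, followup_years, shift) {
  py_r <- n_r * followup_years
  events_r <- pmin(n_r, stats::rpois(length(n_r), (orig_rate + shift) * py_r / 100))
  tibble(
    n = n_r, events = events_r,
    risk = 100 * events_r / n_r,
    rate = 100 * events_r / py_r,
    py = py_r
  )
}

#' Generate a synthetic paired-study portfolio
#'
#' Produces the three pipeline inputs (studies, covariates, checklist) plus a
#' truth ledger recording every latent draw, deterministic given
#' `config$seed`. All outputs pass the [read_study_pairs()] /
#' [read_covariates()] / [read_checklist()] validators with zero rejections.
#'
#' @param config A [sim_config()].
#' @return A list with `studies`, `covariates`, `checklist` (validated
#'   tibbles) and `truth` (list: `config` snapshot and a per-study tibble of
#'   `theta`, `delta`, error components, `sigma`, size ratio, rate shift).
#' @export
generate_portfolio <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  nc <- config$n_comparative
  nd <- config$n_descriptive
  f <- config$shared_error_fraction
  mix <- config$discrepancy_mix
  z <- qnorm(0.975)

  ids <- sprintf("S%03d", seq_len(nc + nd))
  id_c <- ids[seq_len(nc)]
  id_d <- if (nd > 0) ids[nc + seq_len(nd)] else character()

  # --- comparative block ---
  theta <- rnorm(nc, config$mu_theta, config$tau)
  e1 <- sample(seq(config$event_count_range[1], config$event_count_range[2]), nc, replace = TRUE)
  e0 <- sample(seq(config$event_count_range[1], config$event_count_range[2]), nc, replace = TRUE)
  sigma <- sqrt(1 / e1 + 1 / e0)
  eps_sh <- rnorm(nc, 0, sqrt(f) * sigma)
  eps_o <- rnorm(nc, 0, sqrt(1 - f) * sigma)
  eps_r <- rnorm(nc, 0, sqrt(1 - f) * sigma)
  big <- rbinom(nc, 1, mix$pi_big)
  delta <- rnorm(nc, 0, ifelse(big == 1, mix$omega_big, mix$omega_small))
  log_es_o <- theta + eps_sh + eps_o
  log_es_r <- theta + delta + eps_sh + eps_r

  risk1 <- runif(nc, 0.01, 0.2)
  risk0 <- runif(nc, 0.01, 0.2)
  fy <- runif(nc, 1, 3)
  n1 <- pmax(e1, round(e1 / risk1))
  n0 <- pmax(e0, round(e0 / risk0))
  size_z <- rnorm(nc, 0, config$size_ratio_logsd)
  shift_flag <- rbinom(nc, 1, config$dataversion_shift_prob)
  shift <- shift_flag * runif(nc, config$rate_shift_band[1], config$rate_shift_band[2])
  report_p <- rbinom(nc, 1, config$p_report_prob) == 1
  measure <- sample(names(config$measure_probs), nc, replace = TRUE,
                    prob = config$measure_probs)

  o1 <- gen_arm_block(e1, n1, fy)
  o0 <- gen_arm_block(e0, n0, fy)
  r1 <- repro_arm_block(o1$rate, pmax(1L, round(n1 * exp(size_z))), fy, shift)
  r0 <- repro_arm_block(o0$rate, pmax(1L, round(n0 * exp(size_z))), fy, shift)

  p_o <- 2 * pnorm(-abs(log_es_o / sigma))
  p_r <- 2 * pnorm(-abs(log_es_r / sigma))

  comp <- tibble(
    study_id = id_c, design = "comparative", measure = measure,
    orig_n_exp = o1$n, orig_events_exp = o1$events, orig_risk_exp = o1$risk,
    orig_rate_exp = o1$rate, orig_py_exp = o1$py,
    orig_n_ref = o0$n, orig_events_ref = o0$events, orig_risk_ref = o0$risk,
    orig_rate_ref = o0$rate, orig_py_ref = o0$py,
    orig_est = exp(log_es_o), orig_ci_low = exp(log_es_o - z * sigma),
    orig_ci_high = exp(log_es_o + z * sigma),
    orig_p = ifelse(report_p, p_o, NA_real_),
    repro_n_exp = r1$n, repro_events_exp = r1$events, repro_risk_exp = r1$risk,
    repro_rate_exp = r1$rate, repro_py_exp = r1$py,
    repro_n_ref = r0$n, repro_events_ref = r0$events, repro_risk_ref = r0$risk,
    repro_rate_ref = r0$rate, repro_py_ref = r0$py,
    repro_est = exp(log_es_r), repro_ci_low = exp(log_es_r - z * sigma),
    repro_ci_high = exp(log_es_r + z * sigma),
    repro_p = ifelse(report_p, p_r, NA_real_)
  )

  # --- descriptive block (single overall group, no effect estimate) ---
  if (nd > 0) {
    ed <- sample(seq(config$event_count_range[1], config$event_count_range[2]), nd, replace = TRUE)
    riskd <- runif(nd, 0.01, 0.2)
    fyd <- runif(nd, 1, 3)
    nd_arm <- pmax(ed, round(ed / riskd))
    size_zd <- rnorm(nd, 0, config$size_ratio_logsd)
    shift_flagd <- rbinom(nd, 1, config$dataversion_shift_prob)
    shiftd <- shift_flagd * runif(nd, config$rate_shift_band[1], config$rate_shift_band[2])
    od <- gen_arm_block(ed, nd_arm, fyd)
    rd <- repro_arm_block(od$rate, pmax(1L, round(nd_arm * exp(size_zd))), fyd, shiftd)
    desc <- tibble(
      study_id = id_d, design = "descriptive", measure = NA_character_,
      orig_n_exp = od$n, orig_events_exp = od$events, orig_risk_exp = od$risk,
      orig_rate_exp = od$rate, orig_py_exp = od$py,
      repro_n_exp = rd$n, repro_events_exp = rd$events, repro_risk_exp = rd$risk,
      repro_rate_exp = rd$rate, repro_py_exp = rd$py
    )
  } else {
    desc <- NULL
    size_zd <- numeric()
    shiftd <- numeric()
  }

  studies <- bind_rows(comp, desc)
  for (col in setdiff(studies_columns(), names(studies))) studies[[col]] <- NA
  # --- subgroup attributes ---
  ntot <- nc + nd
  studies$funding_source <- sample(c("industry", "public", "mixed"), ntot, replace = TRUE)
  studies$data_source <- sample(c("Medicare", "Optum", "MarketScan", "CPRD"), ntot, replace = TRUE)
  studies$publication_year <- sample(2011:2017, ntot, replace = TRUE)
  studies$journal_impact_band <- sample(c("high", "medium", "low"), ntot, replace = TRUE)
  studies$author_responsive <- rbinom(ntot, 1, 0.53) == 1
  studies$same_group <- rbinom(ntot, 1, 0.05) == 1
  studies <- studies[studies_columns()]

  # --- covariates ---
  ncv <- config$n_covariates
  cs <- config$covariate_shift
  cov_tbl <- tibble(
    study_id = rep(ids, each = ncv),
    covariate = rep(sprintf("cov_%02d", seq_len(ncv)), times = ntot),
    arm = "exp",
    prev_original_pct = runif(ntot * ncv, 2, 98)
  )
  small_shift <- rnorm(ntot * ncv, 0, cs$sd_small)
  large <- rbinom(ntot * ncv, 1, cs$prob_large)
  sign_large <- sample(c(-1, 1), ntot * ncv, replace = TRUE)
  cov_tbl$prev_reproduction_pct <- pmin(100, pmax(0,
    cov_tbl$prev_original_pct - (small_shift + large * sign_large * cs$magnitude_large)))

  # --- checklist ---
  checklist <- generate_checklist(ids, studies$design, config)

  vs <- validate_study_pairs(studies)
  vc <- validate_covariates(cov_tbl)
  vk <- validate_checklist(checklist)
  stopifnot(nrow(vs$rejected) == 0, nrow(vc$rejected) == 0, nrow(vk$rejected) == 0)

  truth <- list(
    config = config,
    studies = tibble(
      study_id = ids,
      design = studies$design,
      theta = c(theta, rep(NA_real_, nd)),
      delta = c(delta, rep(NA_real_, nd)),
      big_component = c(big == 1, rep(NA, nd)),
      eps_shared = c(eps_sh, rep(NA_real_, nd)),
      eps_orig = c(eps_o, rep(NA_real_, nd)),
      eps_repro = c(eps_r, rep(NA_real_, nd)),
      sigma = c(sigma, rep(NA_real_, nd)),
      log_size_ratio = c(size_z, size_zd),
      rate_shift = c(shift, shiftd)
    )
  )

  list(
    studies = structure(studies, rejected = vs$rejected),
    covariates = structure(cov_tbl, rejected = vc$rejected),
    checklist = structure(checklist, rejected = vk$rejected),
    truth = truth
  )
}

generate_checklist <- function(ids, designs, config) {
  items <- checklist_items()
  n <- length(ids)
  resp_levels <- names(config$item_response_probs)
  rows <- lapply(seq_len(n), function(i) {
    design <- designs[i]
    responses <- vapply(seq_len(54), function(j) {
      if (items$applies_to[j] == "comparative" && design == "descriptive") {
        "not_applicable"
      } else {
        sample(resp_levels, 1, prob = config$item_response_probs)
      }
    }, character(1))
    allowed <- allowed_categories(design)
    p <- unname(config$assumption_prob[design])
    flags <- setNames(as.list(rep(FALSE, length(ASSUMPTION_CATEGORIES))),
                      paste0("assume_", ASSUMPTION_CATEGORIES))
    for (cat in allowed) flags[[paste0("assume_", cat)]] <- rbinom(1, 1, p) == 1
    flags[["assume_exposure"]] <- if ("exposure" %in% allowed) flags[["assume_exposure"]] else NA
    c(list(study_id = ids[i], design = design),
      setNames(as.list(responses), sprintf("item_%02d", 1:54)),
      flags)
  })
  bind_rows(lapply(rows, as_tibble))[checklist_columns()]
}

#' Recover generator parameters from a portfolio by method of moments
#'
#' Ledger-blind moment estimators over the comparative studies, using the
#' per-study sampling variances `sigma_i^2` back-calculated from the original
#' CIs. With `lo = log ES_o`, `lr = log ES_r`:
#' \itemize{
#'   \item `Var(lo) = tau^2 + mean(sigma^2)` gives `tau^2`;
#'   \item `Cov(lo, lr) = tau^2 + f * mean(sigma^2)` gives the shared error
#'     fraction `f`;
#'   \item `Var(lo - lr) = omega^2 + 2 (1 - f) mean(sigma^2)` gives the
#'     marginal discrepancy variance `omega^2` (the mixture's components are
#'     not separately identified by second moments).
#' }
#' Standard errors come from a nonparametric bootstrap over studies.
#'
#' @param studies A validated studies tibble from [generate_portfolio()].
#' @param n_boot Bootstrap replicates for the SEs (default 200).
#' @return A tibble with one row per parameter (`tau`, `shared_error_fraction`,
#'   `omega_marginal`): `estimate` and `se`.
#' @export
recover_parameters <- function(studies, n_boot = 200) {
  comp <- as_tibble(studies) %>%
    filter(design == "comparative",
           !is.na(orig_ci_low), !is.na(repro_ci_low))
  if (nrow(comp) < 10) abort("At least 10 comparative studies are required.")
  lo <- log(comp$orig_est)
  lr <- log(comp$repro_est)
  s2 <- se_from_ci(comp$orig_ci_low, comp$orig_ci_high)^2

  moments <- function(idx) {
    lo_i <- lo[idx]; lr_i <- lr[idx]; s2_i <- s2[idx]
    s2bar <- mean(s2_i)
    tau2 <- var(lo_i) - s2bar
    fhat <- (cov(lo_i, lr_i) - tau2) / s2bar
    omega2 <- var(lo_i - lr_i) - 2 * (1 - fhat) * s2bar
    c(tau = sqrt(max(tau2, 0)),
      shared_error_fraction = fhat,
      omega_marginal = sqrt(max(omega2, 0)))
  }

  est <- moments(seq_along(lo))
  boot <- replicate(n_boot, moments(sample.int(length(lo), replace = TRUE)))
  tibble(
    parameter = names(est),
    estimate = unname(est),
    se = apply(boot, 1, sd)
  )
}
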