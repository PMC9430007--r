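# Synthetic portfolio generator and method-of-moments recovery.

noise_free_config <- function(n = 25, seed = 1) {
  sim_config(
    n_comparative = n, n_descriptive = 0, tau = 0,
    shared_error_fraction = 1,
    discrepancy_mix = list(pi_big = 0, omega_small = 0, omega_big = 0),
    size_ratio_logsd = 0, dataversion_shift_prob = 0,
    covariate_shift = list(sd_small = 0, prob_large = 0, magnitude_large = 0),
    seed = seed
  )
}

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(shared_error_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(tau = -0.1), "non-negative")
  expect_error(sim_config(discrepancy_mix = list(pi_big = 0.1, omega_small = 0.5,
                                                 omega_big = 0.1)),
               "omega_small")
  expect_error(sim_config(event_count_range = c(10, 5)), "increasing")
})

test_that("every generated table passes validation with zero rejections", {
  port <- generate_portfolio(sim_config(n_comparative = 40, n_descriptive = 10,
                                        seed = 101))
  expect_equal(nrow(rejection_report(port$studies)), 0)
  expect_equal(nrow(rejection_report(port$covariates)), 0)
  expect_equal(nrow(rejection_report(port$checklist)), 0)
  expect_equal(nrow(port$studies), 50)
  expect_equal(sum(port$studies$design == "comparative"), 40)
  expect_equal(nrow(port$truth$studies), 50)
  # and survives an I/O round-trip through its own schema
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_pairs(port$studies, path)
  expect_equal(nrow(rejection_report(read_study_pairs(path))), 0)
})

test_that("the generator is deterministic given a seed", {
  cfg <- sim_config(n_comparative = 15, n_descriptive = 5, seed = 202)
  p1 <- generate_portfolio(cfg)
  p2 <- generate_portfolio(cfg)
  expect_equal(as.data.frame(p1$studies), as.data.frame(p2$studies))
  expect_equal(as.data.frame(p1$covariates), as.data.frame(p2$covariates))
  expect_equal(as.data.frame(p1$checklist), as.data.frame(p2$checklist))
  expect_equal(p1$truth$studies, p2$truth$studies)
  # byte-identical on disk
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_study_pairs(p1$studies, f1)
  write_study_pairs(p2$studies, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a noise-free configuration yields identical pairs", {
  port <- generate_portfolio(noise_free_config(n = 10, seed = 5))
  rows <- concordance_table(port$studies)
  expect_true(all(abs(rows$rel_magnitude - 1) < 1e-12))
  expect_true(all(rows$abs_log_diff < 1e-12))
  expect_equal(port$studies$orig_n_exp, port$studies$repro_n_exp)
})

test_that("the big-discrepancy mixture fraction matches its probability", {
  mix <- list(pi_big = 0.15, omega_small = 0.02, omega_big = 0.6)
  cfg <- sim_config(n_comparative = 4000, n_descriptive = 0,
                    discrepancy_mix = mix, seed = 303)
  port <- generate_portfolio(cfg)
  delta <- port$truth$studies$delta
  # Monte Carlo oracle: |delta| > 2 * omega_small is almost surely the big
  # component (P(|small| > 2 sd) = 4.6%, P(|big| < 2*0.02) tiny)
  frac <- mean(abs(delta) > 2 * mix$omega_small)
  expected <- mix$pi_big * 2 * pnorm(-2 * mix$omega_small / mix$omega_big) +
    (1 - mix$pi_big) * 2 * pnorm(-2)
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(frac - expected), 3 * se)
  # ledger component labels agree with the draw magnitudes on average
  expect_gt(mean(abs(delta[port$truth$studies$big_component])),
            mean(abs(delta[!port$truth$studies$big_component])))
})

test_that("portfolio correlation approaches 1 as noise is dialled down", {
  cors <- vapply(seq_along(c(1, 2, 3)), function(i) {
    events <- list(c(20L, 60L), c(200L, 600L), c(5000L, 8000L))[[i]]
    cfg <- sim_config(
      n_comparative = 60, n_descriptive = 0, tau = 0.5,
      event_count_range = events, shared_error_fraction = 0,
      discrepancy_mix = list(pi_big = 0, omega_small = 0, omega_big = 0),
      dataversion_shift_prob = 0, seed = 404
    )
    rows <- concordance_table(generate_portfolio(cfg)$studies)
    summarize_agreement(rows)$pearson_unweighted
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.99)
  # with fully shared sampling error and no discrepancy the pairs are exact
  cfg1 <- sim_config(n_comparative = 30, n_descriptive = 0, tau = 0.5,
                     shared_error_fraction = 1,
                     discrepancy_mix = list(pi_big = 0, omega_small = 0, omega_big = 0),
                     dataversion_shift_prob = 0, seed = 405)
  rows1 <- concordance_table(generate_portfolio(cfg1)$studies)
  expect_close(summarize_agreement(rows1)$pearson_unweighted, 1, 1e-9)
})

test_that("data-version shifts land in the configured rate band", {
  cfg <- sim_config(n_comparative = 200, n_descriptive = 0,
                    dataversion_shift_prob = 0.3, seed = 506)
  port <- generate_portfolio(cfg)
  shifts <- port$truth$studies$rate_shift
  hit <- shifts > 0
  expect_gt(sum(hit), 0)
  expect_true(all(shifts[hit] >= 13 & shifts[hit] <= 16))
  # shifted reproductions show markedly higher rates than their originals
  st <- port$studies
  d <- st$orig_rate_exp - st$repro_rate_exp
  expect_lt(mean(d[hit]), mean(d[!hit]))
})

test_that("moment recovery collapses correctly in the noise-free limit", {
  # fully shared error: reproductions duplicate originals exactly, so the
  # discrepancy estimate is exactly zero and the shared fraction exactly one;
  # tau picks up only the sampling fluctuation of the variance moments
  port <- generate_portfolio(noise_free_config(n = 60, seed = 7))
  est <- recover_parameters(port$studies, n_boot = 50)
  expect_lt(est$estimate[est$parameter == "omega_marginal"], 1e-9)
  expect_close(est$estimate[est$parameter == "shared_error_fraction"], 1, 1e-9)
  expect_lt(est$estimate[est$parameter == "tau"], 0.1)
})

test_that("recovery error shrinks roughly like 1/sqrt(n)", {
  err_at <- function(n, seed) {
    cfg <- sim_config(n_comparative = n, n_descriptive = 0, seed = seed)
    est <- recover_parameters(generate_portfolio(cfg)$studies, n_boot = 10)
    abs(est$estimate[est$parameter == "tau"] - 0.5)
  }
  errs_small <- vapply(1:6, function(s) err_at(100, s), numeric(1))
  errs_big <- vapply(1:6, function(s) err_at(1600, 100 + s), numeric(1))
  # 16x the sample should cut the tau error by ~4; allow wide MC slack
  expect_lt(mean(errs_big), mean(errs_small))
})

test_that("recovery demands a minimal portfolio", {
  port <- generate_portfolio(sim_config(n_comparative = 5, n_descriptive = 0,
                                        seed = 8))
  expect_error(recover_parameters(port$studies), "At least 10")
})
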