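# End-to-end pipeline: validate inputs, compute every concordance table and
# summary, render figure analogues, and log a run manifest with file digests
# so reruns are verifiable as byte-identical.

stage_log <- function(stage, n_in, n_out) {
  inform(sprintf("[%s] rows in: %d, rows out: %d", stage, n_in, n_out))
}

as_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else as_tibble(x)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

#' Run the full reproducibility-evaluation pipeline
#'
#' Validates the inputs, computes the per-study effect-concordance table, the
#' cohort-construction concordance tables, the portfolio agreement summary,
#' Bland-Altman limits, the outlier ranking, and (when a checklist is given)
#' the reporting-clarity summary; writes everything to `out_dir` together
#' with figure analogues and a run manifest listing an MD5 digest for every
#' output. The pipeline is a pure function of (inputs, config): rerunning it
#' on the same inputs reproduces identical tables and digests.
#'
#' @param studies Studies table: a path to `studies.csv` or a validated
#'   tibble.
#' @param covariates Optional covariate table (path or tibble).
#' @param checklist Optional checklist table (path or tibble); when omitted
#'   the clarity outputs are skipped and the manifest notes the skip.
#' @param out_dir Output directory (created if needed).
#' @param config A [concordance_config()].
#' @param figures Render figure files (default TRUE).
#' @param figure_formats Character vector of device formats, subset of
#'   `c("png", "svg")`.
#' @return Invisibly, a list with all computed objects plus `manifest`.
#' @export
run_pipeline <- function(studies, covariates = NULL, checklist = NULL,
                         out_dir, config = concordance_config(),
                         figures = TRUE, figure_formats = c("png", "svg")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  studies <- as_input(studies, read_study_pairs)
  if (!is.null(covariates)) covariates <- as_input(covariates, read_covariates)
  if (!is.null(checklist)) checklist <- as_input(checklist, read_checklist)

  conc <- concordance_table(studies, config)
  stage_log("effect_concordance", nrow(studies), nrow(conc))
  readr::write_csv(as_tibble(conc), file.path(out_dir, "concordance.csv"), na = "")

  cohort <- cohort_concordance_table(studies, covariates, config)
  stage_log("cohort_concordance", nrow(studies), nrow(cohort$sizes))
  readr::write_csv(cohort$sizes, file.path(out_dir, "cohort_concordance.csv"), na = "")
  readr::write_csv(bind_rows(risk = cohort$risks, rate = cohort$rates, .id = "metric"),
                   file.path(out_dir, "risk_rate_differences.csv"), na = "")
  if (!is.null(cohort$covariates)) {
    readr::write_csv(cohort$covariates,
                     file.path(out_dir, "covariate_differences.csv"), na = "")
  }

  summary_stats <- summarize_agreement(conc, config)
  write_json_out(unclass(summary_stats), file.path(out_dir, "summary.json"))
  stage_log("agreement_stats", nrow(conc), 1L)

  ba <- bland_altman(conc$log_es_orig, conc$log_es_repro, conc$study_id)
  ba_tbl <- mutate(ba$data, outlier = study_id %in% ba$outside_limits)
  readr::write_csv(ba_tbl, file.path(out_dir, "blandaltman.csv"), na = "")

  k <- min(10L, nrow(conc))
  outlier_ids <- top_outliers(conc, k)
  outliers <- conc[match(outlier_ids, conc$study_id),
                   c("study_id", "rel_magnitude", "signed_log_diff", "abs_log_diff")]
  readr::write_csv(outliers, file.path(out_dir, "outliers.csv"), na = "")

  clarity <- NULL
  if (!is.null(checklist)) {
    clarity <- clarity_summary(checklist, config)
    write_json_out(
      list(
        n_studies = clarity$n_studies,
        per_item = clarity$per_item,
        assumptions_by_design = clarity$assumptions_by_design,
        n_zero_assumption_studies = clarity$n_zero_assumption_studies
      ),
      file.path(out_dir, "clarity_summary.json")
    )
    stage_log("reporting_clarity", nrow(checklist), 1L)
  } else {
    inform("[reporting_clarity] skipped: no checklist supplied")
  }

  results <- list(
    studies = studies, covariates = covariates, checklist = checklist,
    concordance = conc, cohort = cohort, summary = summary_stats,
    bland_altman = ba, outliers = outliers, clarity = clarity,
    config = config
  )

  if (figures) {
    figure_files <- make_figures(results, out_dir, formats = figure_formats)
    results$figure_files <- figure_files
  }

  outputs <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package = "rwerepro",
    version = as.character(packageVersion("rwerepro")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    n_studies_in = nrow(studies),
    n_comparative = sum(studies$design == "comparative"),
    clarity_skipped = is.null(checklist),
    outputs = lapply(outputs, function(f) {
      list(file = f,
           md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  write_json_out(manifest, file.path(out_dir, "manifest.json"))
  results$manifest <- manifest
  invisible(results)
}

save_figure <- function(plot, out_dir, name, formats) {
  files <- character()
  for (fmt in formats) {
    path <- file.path(out_dir, paste0(name, ".", fmt))
    dev <- if (fmt == "png") {
      function(f, ...) grDevices::png(f, width = 1600, height = 1200,
                                      res = 200, type = "cairo")
    } else {
      function(f, ...) grDevices::svg(f, width = 8, height = 6)
    }
    tryCatch({
      dev(path)
      print(plot)
      grDevices::dev.off()
      files <- c(files, path)
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      warn(sprintf("Could not render %s.%s: %s", name, fmt, conditionMessage(e)))
    })
  }
  files
}

#' Render the figure analogues
#'
#' Produces the six standard displays: (1) boxplots of relative sample size
#' by design (log axis, median / quartile / 1.5 IQR whiskers); (2) strip
#' plot of covariate prevalence differences by study; (3) risk and rate
#' calibration scatters with the identity diagonal; (4) the distribution of
#' relative effect magnitude (log axis); (5) the calibration scatter of log
#' reproduced versus log original effects with 95% CI error bars, null lines,
#' the identity diagonal, and the 10 most extreme outliers highlighted; and
#' (6) the Bland-Altman plot with the mean-difference line and limits at
#' +/- 2 SD. Figures with no underlying data are skipped with a notice.
#'
#' @param results The list returned by [run_pipeline()] (or an equivalent
#'   list with `studies`, `concordance`, `cohort`, `bland_altman`).
#' @param out_dir Output directory.
#' @param formats Subset of `c("png", "svg")`.
#' @return Invisibly, a character vector of written files.
#' @export
make_figures <- function(results, out_dir, formats = c("png", "svg")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plots <- build_figures(results)
  files <- character()
  for (name in names(plots)) {
    if (is.null(plots[[name]])) {
      inform(sprintf("[figures] %s skipped: no data", name))
      next
    }
    files <- c(files, save_figure(plots[[name]], out_dir, name, formats))
  }
  invisible(files)
}

# Build the ggplot objects without touching any device (unit-testable).
build_figures <- function(results) {
  conc <- results$concordance
  sizes <- results$cohort$sizes
  covs <- results$cohort$covariates
  risks <- results$cohort$risks
  rates <- results$cohort$rates
  ba <- results$bland_altman

  log_breaks <- c(0.25, 0.5, 1, 2, 4)

  fig1 <- if (!is.null(sizes) && nrow(sizes) > 0) {
    ggplot2::ggplot(sizes, ggplot2::aes(x = design, y = rel_sample_size)) +
      ggplot2::geom_boxplot(outlier.shape = 1) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
      ggplot2::scale_y_log10(breaks = log_breaks, labels = log_breaks) +
      ggplot2::labs(x = NULL, y = "Relative sample size (original / reproduction)",
                    title = "Relative magnitude of sample size")
  }

  fig2 <- if (!is.null(covs) && nrow(covs) > 0) {
    ggplot2::ggplot(covs, ggplot2::aes(x = study_id, y = diff_pct)) +
      ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.5, size = 0.8) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
      ggplot2::labs(x = "Study", y = "Prevalence difference (orig - repro), pct points",
                    title = "Baseline characteristic differences") +
      ggplot2::theme(axis.text.x = ggplot2::element_blank())
  }

  cal <- NULL
  if (!is.null(risks) && (nrow(risks) > 0 || nrow(rates) > 0)) {
    studies <- as_tibble(results$studies)
    add_levels <- function(d, field) {
      idx <- match(d$study_id, studies$study_id)
      level <- function(version) {
        vapply(seq_len(nrow(d)), function(i) {
          studies[[paste0(version, "_", field, "_", d$arm[i])]][idx[i]]
        }, numeric(1))
      }
      d$orig <- level("orig")
      d$repro <- level("repro")
      d
    }
    cal_data <- bind_rows(
      Risk = add_levels(risks, "risk"),
      Rate = add_levels(rates, "rate"),
      .id = "metric"
    )
    cal_data <- cal_data[!is.na(cal_data$orig) & !is.na(cal_data$repro), ]
    if (nrow(cal_data) > 0) {
      cal <- ggplot2::ggplot(cal_data, ggplot2::aes(x = repro, y = orig)) +
        ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
        ggplot2::geom_point(alpha = 0.6, shape = 1) +
        ggplot2::facet_wrap(~metric, scales = "free") +
        ggplot2::labs(x = "Reproduction", y = "Original",
                      title = "Calibration of outcome risks and rates")
    }
  }

  fig4 <- if (!is.null(conc) && nrow(conc) > 0) {
    ggplot2::ggplot(conc, ggplot2::aes(x = rel_magnitude)) +
      ggplot2::geom_histogram(bins = 30, colour = "white") +
      ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
      ggplot2::scale_x_log10(breaks = log_breaks, labels = log_breaks) +
      ggplot2::labs(x = "Relative magnitude (original / reproduction)",
                    y = "Studies",
                    title = "Distribution of relative effect magnitude")
  }

  fig5 <- if (!is.null(conc) && nrow(conc) > 0) {
    k <- min(10L, nrow(conc))
    out_ids <- top_outliers(conc, k)
    dat <- mutate(conc, outlier = study_id %in% out_ids)
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = log_es_orig, y = log_es_repro)) +
      ggplot2::geom_abline(linetype = "dashed") +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
      ggplot2::geom_point(ggplot2::aes(colour = outlier), show.legend = FALSE) +
      ggplot2::scale_colour_manual(values = c(`FALSE` = "black", `TRUE` = "red")) +
      ggplot2::labs(x = "log effect size, original", y = "log effect size, reproduction",
                    title = "Calibration of log effect sizes")
    if (all(!is.na(conc$se_orig)) && all(!is.na(conc$se_repro))) {
      z <- qnorm(0.975)
      p <- p +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = log_es_repro - z * se_repro,
                                            ymax = log_es_repro + z * se_repro),
                               linewidth = 0.2, alpha = 0.4) +
        ggplot2::geom_errorbarh(ggplot2::aes(xmin = log_es_orig - z * se_orig,
                                             xmax = log_es_orig + z * se_orig),
                                linewidth = 0.2, alpha = 0.4)
    }
    p
  }

  fig6 <- if (!is.null(ba)) {
    ggplot2::ggplot(ba$data, ggplot2::aes(x = pair_mean, y = pair_diff)) +
      ggplot2::geom_point(shape = 1) +
      ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "blue") +
      ggplot2::geom_hline(yintercept = c(ba$lower_limit, ba$upper_limit),
                          colour = "red") +
      ggplot2::labs(x = "Mean of log effect sizes",
                    y = "Difference in log effect size (orig - repro)",
                    title = "Bland-Altman plot of log effect sizes")
  }

  list(fig1_sample_size = fig1, fig2_covariates = fig2,
       fig3_risk_rate_calibration = cal, fig4_rel_magnitude = fig4,
       fig5_effect_calibration = fig5, fig6_bland_altman = fig6)
}
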