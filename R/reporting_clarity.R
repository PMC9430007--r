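# Scoring of the 54-item reporting-clarity instrument. Items map onto six
# study-parameter categories (index date, inclusion-exclusion, exposure,
# outcome, follow-up, covariates); descriptive studies have no exposure, so
# their allowed category set has five members. The item-to-category mapping
# is shipped as an editable schema file, not hard-coded.

#' The item-to-category schema of the reporting checklist
#'
#' Loads the mapping of the 54 reporting items onto study-parameter
#' categories, with each item's applicability rule (`both` or
#' `comparative`). The shipped file is a synthetic reconstruction of a
#' consensus reporting instrument (the real instrument's wording is not
#' redistributable); replace it with your own mapping by passing `path`.
#'
#' @param path Optional path to an alternative schema CSV with columns
#'   `item_id`, `label`, `category`, `applies_to`.
#' @return A 54-row tibble.
#' @export
checklist_items <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "checklist_items.csv", package = "rwerepro")
  }
  items <- readr::read_csv(path, col_types = "cccc", progress = FALSE)
  needed <- c("item_id", "label", "category", "applies_to")
  if (!all(needed %in% names(items))) {
    abort("Checklist schema must have columns item_id, label, category, applies_to.")
  }
  if (!all(items$category %in% ASSUMPTION_CATEGORIES)) {
    abort("Unknown category in checklist schema.")
  }
  items
}

allowed_categories <- function(design) {
  if (design == "descriptive") setdiff(ASSUMPTION_CATEGORIES, "exposure")
  else ASSUMPTION_CATEGORIES
}

#' Number of categories in which the reproduction made assumptions
#'
#' Counts the study-parameter categories flagged as requiring at least one
#' assumption by the reproduction team: range 0-6 for comparative studies,
#' 0-5 for descriptive studies (which have no exposure category). Flagging
#' the exposure category on a descriptive study is a validation error.
#'
#' @param records A validated checklist tibble ([read_checklist()]).
#' @return A tibble with `study_id`, `design`, `n_assumption_categories`.
#' @export
assumption_category_count <- function(records) {
  records <- as_tibble(records)
  counts <- vapply(seq_len(nrow(records)), function(i) {
    row <- as.list(records[i, ])
    allowed <- allowed_categories(row$design)
    bad <- setdiff(ASSUMPTION_CATEGORIES, allowed)
    flagged_bad <- vapply(bad, function(cat) isTRUE(row[[paste0("assume_", cat)]]), logical(1))
    if (any(flagged_bad)) {
      abort(sprintf("Study %s: category '%s' not allowed for %s studies.",
                    row$study_id, bad[flagged_bad][1], row$design))
    }
    sum(vapply(allowed, function(cat) isTRUE(row[[paste0("assume_", cat)]]), logical(1)))
  }, integer(1))
  tibble(study_id = records$study_id, design = records$design,
         n_assumption_categories = counts)
}

#' Summary of reporting clarity across studies
#'
#' Per-item reporting proportions use the denominator rule
#' `reported / (responses - not_applicable)`, so adding a `not_applicable`
#' response never changes an item's proportion. By default
#' `partially_reported` counts as not reported (conservative); flip
#' `partially_counts_as_reported` in the config to change that. Assumption
#' burden is summarised as the median and IQR (linear-interpolation
#' quantiles) of the per-study category counts, stratified by design, plus
#' the count of studies with no assumption in any category.
#'
#' @param records A validated checklist tibble.
#' @param config A [concordance_config()].
#' @return A list of class `clarity_summary` with `n_studies`, `per_item`
#'   (tibble: item, counts, denominator, proportion), `assumptions_by_design`
#'   (median/IQR per design), and `n_zero_assumption_studies`.
#' @export
clarity_summary <- function(records, config = concordance_config()) {
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("At least one checklist record is required.")
  item_cols <- sprintf("item_%02d", 1:54)

  long <- tidyr::pivot_longer(records[c("study_id", item_cols)],
                              all_of(item_cols),
                              names_to = "item_id", values_to = "response")
  counted <- if (config$partially_counts_as_reported) {
    c("reported", "partially_reported")
  } else {
    "reported"
  }
  per_item <- long %>%
    group_by(item_id) %>%
    summarise(
      n_reported = sum(response %in% counted),
      n_partially = sum(response == "partially_reported"),
      n_not_reported = sum(response == "not_reported"),
      n_not_applicable = sum(response == "not_applicable"),
      denominator = sum(response != "not_applicable"),
      prop_reported = ifelse(denominator > 0, n_reported / denominator, NA_real_),
      .groups = "drop"
    )

  counts <- assumption_category_count(records)
  q <- function(v, p) unname(quantile(v, p, type = 7))
  assumptions_by_design <- counts %>%
    group_by(design) %>%
    summarise(
      n = n(),
      median = q(n_assumption_categories, 0.5),
      q1 = q(n_assumption_categories, 0.25),
      q3 = q(n_assumption_categories, 0.75),
      .groups = "drop"
    )

  structure(
    list(
      n_studies = nrow(records),
      per_item = per_item,
      assumptions_by_design = assumptions_by_design,
      n_zero_assumption_studies = sum(counts$n_assumption_categories == 0)
    ),
    class = "clarity_summary"
  )
}
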