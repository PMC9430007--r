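---
title: "Measuring the reproducibility of real-world evidence studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the reproducibility of real-world evidence studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwerepro)
```

## The problem

Database studies of medical-product effects — cohort studies run on claims
or electronic health record data — are increasingly used in regulatory and
coverage decisions. Because the analytic cohort is carved out of
longitudinal source tables by thousands of design decisions (index-date
anchoring, inclusion-exclusion windows, exposure and outcome algorithms,
covariate assessment), a second team re-implementing a study from its
publication alone will rarely land on the identical result. The distance
between the original and the independent reproduction is a direct measure
of how completely the study was reported; measuring it across a portfolio
of studies calibrates how much trust a methods section alone can support.

`rwerepro` operationalises that measurement. One unit of analysis is a
*study pair*: the published result block and the reproduced result block
for the same study question. All effect-size work happens on the natural
log of the ratio-scale estimate (HR, RR, or OR), where the null is 0 and
sampling error is approximately normal.

## Per-study metrics and their conventions

Let `ES_o`, `ES_r` be the original and reproduced estimates with 95% CIs
`(L, U)` and `se = (log U − log L) / (2 z_{0.975})`.

* **Relative magnitude** `ES_o / ES_r` and the **absolute log-difference**
  `|log ES_o − log ES_r|`. The ≤ 0.1 / ≤ 0.2 close-agreement flags are
  *inclusive*; 0.1 corresponds to roughly a 10% difference in the effect
  estimate.
* **Closer to null** compares `|log ES|`; a tie is declared below `1e-12`
  on that scale. The strict comparison matters because the headline split
  (what fraction of reproductions is attenuated toward the null) is read
  as evidence against systematic exaggeration in originals; ties are
  essentially impossible on real data and the tolerance only protects the
  degenerate identical-pair case.
* **Same side of null** comes in two strengths: points only, and points
  plus both CIs excluding 1.0 on the same side. A point exactly at the
  null is treated as agreeing with either side.
* **CI overlap** uses closed intervals — touching endpoints count as
  overlap, conservative toward agreement.
* **Significance discordance** is `p ≤ 0.01` in one study against
  `p > 0.05` in the other, in either direction; both thresholds sit in
  `concordance_config()`. When a study did not print a p-value we
  back-calculate it from the CI under the log-normal approximation and
  mark the row's provenance (`from_ci`). Printed p-values always take
  precedence; all tests are treated as two-sided (sources that reported
  one-sided tests are not distinguishable from the result block alone).

## Portfolio statistics

Correlations (Pearson, Spearman) are computed on `log ES`, unweighted and
inverse-variance weighted. Two choices here were genuinely open:

* **The IVW weight.** A study pair has two standard errors. The default
  weight is the pair-level precision `1 / (se_o² + se_r²)` — the precision
  of the observed log-difference, which is the quantity whose
  reproducibility is being weighted. `concordance_config(ivw_weighting =
  "original")` switches to `1 / se_o²` for sensitivity analyses.
* **Weighted Spearman.** Defined as the weighted Pearson correlation of
  mid-ranks (average ranks under ties). Weighting the ranks rather than
  rank-transforming a weighted statistic is an assumption; it reduces to
  the classical Spearman coefficient under equal weights, which is the
  property the tests pin down.

The **ICC** is the one-way random-effects ICC(1): original and reproduction
are an unordered pair of measurements of the same study, with no "rater"
effect that would justify a two-way model. From the one-way ANOVA with k = 2
measurements, `ICC = (MSB − MSW) / (MSB + MSW)`; the 95% CI uses the F
pivot with `(n − 1, n)` degrees of freedom. The estimator is switchable in
principle but ICC(1) is the defensible default for this design.

**Bland-Altman** limits are `mean(d) ± 2 sd(d)` on `d = log ES_o − log
ES_r` with the sample (n − 1) SD — the multiplier is exactly 2, not 1.96,
matching the conventional agreement-plot construction the output figures
draw.

**Quantiles** everywhere are linear-interpolation type 7 (R's default).
This has to be stated because medians and IQR endpoints of the relative
magnitude are headline numbers, and quantile conventions differ in the
second decimal at portfolio sizes near 100.

**Outliers** are ranked by `|Δ log ES|` descending with lexicographic
study-id tie-breaks, so the top-k set is deterministic.

**Subgroup exploration** (`subgroup_variation()`) is a classical one-way
ANOVA of `|Δ log ES|` on one attribute at a time, deliberately without
multiple-testing adjustment: it is descriptive triage, not confirmatory
inference, and the output carries a `degenerate` flag with p = 1 when all
values are identical.

Proportions are always reported with their denominators: missing CI or
p-value information shrinks a denominator rather than being imputed.

## Cohort concordance

Relative sample size is the ratio of summed arm sizes, original over
reproduction; ratios strictly below 1/2 or above 2 are flagged extreme
(the wording "less than half or more than 2 times" reads as strict, and a
ratio of exactly 2.0 is not flagged). Covariate prevalence and outcome
risk differences are in percentage points, rate differences in events per
100 person-years (`arm_result()` rescales other denominators at
construction), all taken original minus reproduction, with strict `> 10`
large-difference flags — so a boundary difference of exactly 10 is not
large. Comparative studies contribute one risk/rate entry per exposure
group; descriptive studies one overall.

## Reporting-clarity scoring

The 54-item instrument maps onto six study-parameter categories (index
date, inclusion-exclusion, exposure, outcome, follow-up, covariates);
descriptive studies have no exposure category. The shipped
`checklist_items.csv` is a *synthetic reconstruction* of such a consensus
instrument — the mapping is data, not code, and is meant to be replaced
with a team's own versioned schema. Per-item reporting proportions use the
denominator `responses − not_applicable`, so marking an item inapplicable
never moves its proportion; `partially_reported` counts as *not* reported
by default (conservative), switchable in the config. The assumption burden
per study is the count of categories in which the reproduction team made
at least one assumption, summarised as median and IQR by design.

## The synthetic generator

`generate_portfolio()` emulates the statistical structure of a reproduced
portfolio at the summary level (never individual claims):

```
theta_i   ~ N(mu_theta, tau²)                true log effect
sigma_i   = sqrt(1/e1 + 1/e0)                sampling SE from original arm
                                             event counts (log-rate-ratio
                                             approximation, swappable)
log ES_o  = theta + eps_shared + eps_o
log ES_r  = theta + delta + eps_shared + eps_r
delta_i   ~ (1 − pi_big) N(0, omega_small²) + pi_big N(0, omega_big²)
```

`eps_shared` carries a fraction `f` of the sampling variance common to
both analyses — both teams draw cohorts from the *same* source data, so
their sampling errors cannot be independent. The discrepancy `delta` is a
two-component mixture: small perturbations from minor implementation
differences for most studies, plus a rare wide component producing the
extreme outliers that dominate real portfolios. Reproduction cohort sizes
are log-normal around the original; with small probability a study's
reproduction hits a retroactive *data-version shift* that raises all its
outcome rates by a Uniform(13, 16) per-100-person-year amount (the
magnitude of a documented real-world case in which an updated data version
captured an older, sicker population); covariate prevalences get a small
Gaussian perturbation plus a rare ±20-point shift (the magnitude of a
mis-specified comorbidity-score algorithm is the motivating case, where
97% vs 12% was observed); and p-values are masked at random since many
publications omit them. Reproduced event counts are Poisson draws at the
(possibly shifted) original rate, which produces the funnel shape —
larger risk/rate levels reproduce with larger absolute differences.

Default parameter choices, made once: 118 comparative + 32 descriptive
studies (a realistic 80/20 portfolio split); `tau = 0.5` (true HRs mostly
between 0.37 and 2.7); arm event counts 20–500 (per-study log SEs around
0.1–0.3, typical of published database studies); `f = 0.5` (half the
sampling variance shared — unknown in reality, recoverable from the data,
see below); `pi_big = 0.1`, `omega_small = 0.1`, `omega_big = 0.5`
(marginal discrepancy SD ≈ 0.18, giving a median `|Δ log ES|` near 0.15);
`size_ratio_logsd = 0.45` (a compromise between a reported interquartile
ratio band of roughly 0.7–1.3, which alone implies ≈ 0.39, and a ~20%
rate of beyond-half/double extremes, which implies ≈ 0.55 — real size
ratios are heavier-tailed than log-normal); data-version shift probability
0.05 (no empirical prevalence exists for such events; this is an
assumption and is flagged as such); covariate large-shift probability
0.17. These defaults are a *stated world*, not a calibration: the
acceptance-level smoke test only asserts wide neighbourhoods (median
relative magnitude within 0.8–1.25, CI overlap above 60%).

What the generator does **not** emulate: between-arm confounding and its
correction (effects are drawn, not estimated from cohorts), correlation
between reporting clarity and reproducibility (checklist responses are
independent of `delta`), heavy-tailed size ratios, multiple outcomes per
study, and any within-data-source clustering. A green test on synthetic
data therefore establishes computational correctness of the metrics and
the plumbing, not that real portfolios behave like the model.

### Parameter recovery

`recover_parameters()` inverts the model by method of moments, blind to
the truth ledger, using per-study `sigma_i²` back-calculated from the CIs:

```
Var(log ES_o)              = tau² + mean(sigma²)
Cov(log ES_o, log ES_r)    = tau² + f · mean(sigma²)
Var(log ES_o − log ES_r)   = omega² + 2 (1 − f) mean(sigma²)
```

solved in that order; SEs by nonparametric bootstrap over studies. Second
moments identify only the *marginal* discrepancy variance
`omega² = (1 − pi_big) omega_small² + pi_big omega_big²`, not the mixture
components individually — the mixture tail is instead checked directly
against the truth ledger in the test suite. At 2,000 studies each
recovered parameter sits within Monte Carlo error of truth; at a realistic
150 studies the shared-error fraction is weakly identified (its bootstrap
SE approaches 1), which is itself an honest statement about how little a
small portfolio says about error sharing.

## Input format and I/O conventions

One CSV dialect (UTF-8, comma, `.` decimal, required header), no sniffing.
The studies table is wide, one row per study pair, with a fixed two-arm
block per version (`_exp` exposure, `_ref` reference listed last) — a
stable reference arm without a long-format join. Absent numeric values are
empty strings, never 0: absence is meaningful (an unreported p-value is
data). Effects are stored on the ratio scale; logs are taken at
computation time only. Doubles are parsed with correctly-rounded `strtod`,
so write → read → write is byte-identical at full precision — the property
the run manifest's digests rely on. Validation is total: every input row
lands either in the record set or in the rejection report with its
study id and the violated invariant, and the two counts always sum to the
input rows. The checklist schema ships as CSV (machine-readable, no YAML
dependency in the R stack used here).

## Known limitations

* All CI-based quantities assume log-normal sampling of ratio estimates;
  exact CIs from sparse-event methods will give slightly inconsistent
  back-calculated p-values.
* The two-arm wide layout cannot represent studies comparing three or more
  exposure groups; such studies must be entered as their primary contrast.
* ICC confidence intervals rely on F quantiles and are approximate for
  portfolios under ~15 studies.
* `recover_parameters()` assumes the generator's own error structure; on
  real portfolios it estimates the analogous moments but their
  interpretation as "shared error" inherits the model's assumptions.
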