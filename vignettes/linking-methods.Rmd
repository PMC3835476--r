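---
title: "IRT-based linking of the PF-10 and HAQ-DI: models, procedure and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IRT-based linking of the PF-10 and HAQ-DI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfhaqlink)
```

## The problem

The SF-36 physical functioning scale (PF-10) and the Health Assessment
Questionnaire disability index (HAQ-DI) are the two most widely used
self-reported physical-function measures in rheumatoid arthritis, but they are
not directly comparable: the PF-10 sums ten 3-category items into a 0–100
score (higher = better function, 21 attainable values), while the HAQ-DI
averages eight category scores — each the maximum of its 4-category items,
optionally raised for aids/devices use — into a 0–3 index (higher = more
disability, 25 attainable values). A *crosswalk* converts a total score on one
instrument into the best-matching total score on the other, enabling
group-level comparison and pooling of studies that used different instruments.

This package implements the full linking pipeline: instrument scoring,
co-calibration of both scales under nested polytomous IRT models, construction
of sum-score concordance tables by nearest-EAP matching, item-fit diagnostics,
and the agreement/longitudinal-validity battery used to judge whether a
crosswalk is fit for group-level use. The published RA crosswalk ships as a
working converter (`published_crosswalk()`), and a synthetic-data generator
makes every stage testable without access to the original registry data.

## Models

All models are adjacent-category logit models for ordered polytomous
responses. For an item with categories $k = 0, \dots, m_j - 1$, discrimination
$a_j$ and thresholds $b_{j1}, \dots, b_{j,m_j-1}$,

$$P(X_j = k \mid \theta) \;=\;
\frac{\exp\!\big(\sum_{h \le k} a_j(\theta - b_{jh})\big)}
     {\sum_{c=0}^{m_j-1} \exp\!\big(\sum_{h \le c} a_j(\theta - b_{jh})\big)}.$$

* **PCM** (partial credit model): all $a_j = 1$. The summed score is then a
  sufficient statistic for $\theta$, which makes sum-score linking exact in a
  precise sense: every response pattern with the same sum has the same EAP
  (`sum_score_eap_table()` is tested against `eap_pattern()` on this
  property).
* **GPCM**: one free discrimination per item.
* **MIRT2**: a between-item two-dimensional GPCM, PF-10 items on one standard
  normal dimension and HAQ category scores on the other, with the latent
  correlation $\rho$ estimated. This relaxes the assumption that both scales
  measure literally the same trait.

Throughout, $\theta$ increases with *disability*. PF-10 items are therefore
reverse-coded (0 = no limitation, 2 = limited a lot) before calibration;
`build_crosswalk()` enforces this.

## Estimation

Structural parameters are estimated by marginal maximum likelihood with an EM
algorithm (`fit_calibration()`):

* **Quadrature.** A fixed rectangular grid of 61 equally spaced nodes on
  $[-6, 6]$ per dimension, with standard-normal weights renormalised to 1
  (for MIRT2, a product grid with bivariate-normal weights at the current
  $\rho$). For items with at most 4 categories the integrands are smooth and
  rapidly decaying, and this simple rule is accurate far beyond the needs of
  the application: pattern EAPs computed on the default grid agree with a
  10-times-finer grid to better than $10^{-6}$ (tested).
* **Identification.** The latent prior is fixed standard normal on each
  dimension; under the PCM all discriminations are fixed at 1.
* **M-step.** Per-item maximisation of the expected complete-data
  log-likelihood by BFGS with analytic gradients (a partial M-step of at most
  10 BFGS iterations; the update is rejected if it would decrease the
  expected log-likelihood, so EM monotonicity is preserved — the test suite
  checks the observed-data log-likelihood trace never decreases by more than
  $10^{-8}$). BFGS was chosen over a hand-rolled Newton step because it is
  robust when the expected-information matrix is ill-conditioned far from the
  optimum; both maximise the same function.
* **Convergence.** Maximum absolute parameter change below $10^{-4}$, capped
  at 2000 iterations. The cap is generous on purpose: EM's linear convergence
  rate occasionally needs 600+ iterations on clean, well-conditioned data,
  and a tight cap would turn routine fits into errors. Non-convergence is an
  error carrying the log-likelihood trace.
* **$\rho$ in MIRT2.** During EM, $\rho$ is updated by the closed-form
  maximiser of the expected bivariate-normal log-likelihood given the
  posterior cross-moments (fast, monotone). The reported estimate is then a
  profile-likelihood grid search with item parameters held fixed: a coarse
  grid over $(-0.95, 0.95)$ in steps of 0.01, refined once to steps of 0.001
  around the best value. The grid search is the estimator of record; the
  moment update is a speed device during iterations.
* **Unobserved categories** are collapsed into their nearest observed
  neighbour with a warning (strict mode errors instead). Collapsing changes
  the meaning of the affected item's thresholds and is recorded on the fitted
  object.

EAP scoring (`eap_pattern()`, `eap_matrix()`) evaluates the posterior on the
same grid. Sum-score EAP tables use the Lord–Wingersky recursion
(`sum_score_posterior()`): the conditional distribution of the summed score at
every node, convolved item by item, then
$\hat\theta(s) = \sum_q \theta_q P(s \mid \theta_q) w_q \big/ \sum_q P(s \mid \theta_q) w_q$.
The recursion is verified against exhaustive pattern enumeration on toy
instruments to $10^{-10}$.

For the between-item MIRT2 model, each instrument's sum-score table is
computed on its own dimension: given only that instrument's responses, the
other dimension integrates out of the bivariate prior exactly, leaving the
standard-normal margin, so the 1-D computation is identical to the 2-D one.
Because both dimensions are estimated concurrently under the joint prior, the
two tables are treated as sitting on one comparable EAP scale and linking
minimises the direct EAP distance — the same rule as in the unidimensional
models. (Conditional-expectation linking given the other dimension would be an
alternative reading; direct distance was chosen as the plainer interpretation
and is what `nearest_link()` implements.)

## Crosswalk construction

`build_crosswalk()` chains the published procedure: score HAQ categories (SDI
or ADI), reverse-code the PF-10, co-calibrate all 18 "items" jointly,
recompute per-instrument sum-score EAP tables with the joint item parameters
held fixed, then link every attainable total score to the total score on the
other instrument with the nearest EAP. Two conventions matter and are tested:

* **Ties** (two candidate scores equidistant in EAP) break toward the score
  indicating *better* function — lower HAQ, higher PF-10. The source
  procedure is silent on ties; a fixed convention keeps construction
  deterministic.
* **Boundaries clip.** A score whose EAP lies beyond the other instrument's
  most extreme EAP maps to that extreme score (HAQ-DI ≥ 2.75 maps to PF-10
  0; PF-10 95 and 100 map to HAQ-DI 0.000 in the published tables). The
  crosswalk never extrapolates beyond the attainable sets, and the
  `crosswalk` constructor enforces totality and monotonicity.

The packaged published crosswalk is shipped as data (both HAQ scoring
variants, with norm-based PF-10 companions) and is **not** recomputed at
install time — it is the published mapping, not a simulation product.

### Norm-based PF-10 scoring

`pf10_norm_based()` maps the 0–100 raw score to the T-metric
($50 + 10(\text{raw} - \mu)/\sigma$ in a 1998 US general-population
reference). The reference moments are not printed as constants anywhere in
the source material, so the defaults are estimated from the 21 published
(raw, norm-based) pairs — by least squares *constrained to reproduce every
printed value to one decimal*. Plain least squares misses two printed values
by one rounding unit (it predicts 15.0 and 17.1 where the table prints 14.9
and 17.0), because the printed column carries the reference population's own
rounding; the constrained fit honours it. The constants are frozen in
`default_norm_coefficients()` with a regeneration script
(`scripts/regenerate-norm-coefficients.R`), and users can override them.

## Item fit

`item_fit()` groups persons into low/average/high EAP tertiles and compares
the observed mean item score with the model-expected mean in each group, the
expectation being averaged over each member's full posterior (consistent with
marginal estimation, rather than plugging in the point EAP). The effect size
$ES = |\text{observed} - \text{expected}|/m_j$ is the primary criterion: fit
is acceptable when every ES is below 0.10, which corresponds to
observed-vs-expected score-frequency differences of 2.5% for 4-category and
3.33% for 3-category items (`es_to_frequency()`).

Grouping uses value-based (type-1) quantile cutpoints rather than rank-based
splitting: EAPs are functions of the response pattern, so exact ties are
common, and keeping tied EAPs in one group makes the diagnostic invariant to
person relabeling and to sample duplication (both tested). A chi-square-type
statistic (quadratic form of grouped score residuals with the model-implied
variance as plug-in covariance) accompanies the effect sizes; it approximates
the Lagrange-multiplier tests used for polytomous items, whose exact
asymptotic covariance is out of scope — the ES criterion is the gate.

## Validation battery

* `icc_a1()` — ICC(A,1), the two-way, absolute-agreement, single-measure
  intraclass correlation, computed from the two-way mean squares, with the
  F-distribution confidence interval (Satterthwaite df). Agreement ≥ 0.70 is
  flagged adequate for group-level comparisons. Whether the original CIs were
  F-based is unstated; the F interval is the standard choice for (A,1).
* `bland_altman()` — observed-minus-predicted differences against pair means,
  with limits of agreement $\bar d \pm 1.96\, s_d$. The observed-minus-
  predicted convention is used throughout.
* `classify_responder()` — DAS28 good response: improvement ≥ 1.2 *and*
  final score ≤ 3.2. DAS28 values are taken as given; computing DAS28 from
  joint counts is out of scope.
* `effect_size_change()` — Cohen's d for longitudinal change, mean change
  over the *baseline* SD by default (the common responsiveness convention;
  the change-score SD is available via an argument since the source does not
  state its choice), signed so improvement is positive.
* `relative_validity()` — the ratio of one-way ANOVA F statistics (predicted
  vs observed change on responder group) with a 95% bias-corrected and
  accelerated bootstrap interval: persons are resampled B = 2000 times with a
  fixed, recorded seed; the acceleration constant comes from the jackknife; a
  resample that empties a group is redrawn and counted. With zero bias and
  acceleration the interval reduces to the percentile interval (tested).

## The synthetic-data generator

No public version of the calibration registry exists, so
`simulate_pf10_haq()` and `simulate_longitudinal()` emulate its *structure*:

* latent disability standard normal; under the two-dimensional configuration
  the PF-10 and HAQ dimensions correlate at $\rho = 0.73$ by default;
* stylized item thresholds with the PF-10 items targeting better levels of
  function and the HAQ categories shifted toward worse function (locations
  $-1.8$ to $0.9$ vs $-0.9$ to $1.8$), mirroring the instruments' published
  test-information targeting. These layouts are *stylized, not estimates* —
  the original item parameters are not available to this package;
* HAQ items drawn per item within categories (small deterministic location
  jitter within a category), then scored by the real max-and-aids rule, so
  SDI ≥ ADI holds by construction;
* aids/devices flags from a per-category logistic model in latent disability,
  $P(\text{flag}) = \operatorname{logit}^{-1}(-2 + 1 \cdot \theta)$: a slope
  of 1 concentrates SDI–ADI differences at worse function, and the intercept
  gives a modest overall prevalence, as observed in RA cohorts;
* scenario defaults: a calibration-like cohort of n = 1791 at latent mean 0,
  and a cross-validation-like cohort of n = 532 (baseline) / 276
  (longitudinal) at latent mean $-0.5$ — an early-RA population with better
  baseline function;
* the longitudinal block draws good responders with probability 134/276 and
  gives them a mean latent improvement of 0.9 SD (others 0.05), with change
  noise SD 0.3; DAS28 pairs are generated to satisfy the responder rule
  consistently with the drawn labels. These values were chosen once so that
  total change effect sizes land in the 0.3–0.6 range typical of 6-month
  treat-to-target cohorts.

What passing tests on these data do and do not show: they verify the
*machinery* — estimator consistency (threshold RMSE < 0.10 and $\hat\rho$
within ±0.05 at n = 2000), the self-consistency of fit diagnostics, the
near-identity of crosswalks built under the three nested models on
unidimensional data, and downstream observed-vs-predicted ICCs in the 0.7–0.9
range. They do not reproduce the published item parameters or crosswalk
entries, which depend on the original registry sample; the published mapping
is packaged as data for exactly that reason. Real data also carry features
the generator omits: local dependence within HAQ categories beyond the shared
location, differential item functioning across subgroups, missing-data
mechanisms, and floor/ceiling clustering.

## Numerical and policy choices

* Missing data: complete-case scoring by default (the source procedure never
  describes imputation); the conventional relaxed HAQ rule (score when ≥ 6 of
  8 categories are present, averaging the present ones) is available but off
  by default. Missing item responses are skipped in EAP scoring; an
  all-missing pattern is an error.
* The HAQ item-to-category partition defaults to the standard
  2/2/3/2/3/2/3/3 layout (`haq_categories()`), and the SDI rule raises a
  flagged category to 2 only when its item maximum is below 2 — the standard
  HAQ convention.
* Problem sizes in the test suite (20 replicates at n = 2000 for recovery,
  20 at n = 1791 for fit diagnostics, one 1791-person cohort for the
  cross-model comparison) were chosen as the smallest designs that estimate
  the checked quantities stably; medians over replicates are compared, not
  single draws.
* All randomness is seed-controlled; crosswalk construction itself is
  deterministic given responses, model and scoring method.

## Known limitations

* The LM-type fit statistic is an approximation; its p-values are indicative
  and the ES criterion is the operative rule.
* Crosswalks are for group-level use. Individual-level conversion is
  explicitly out of scope: limits of agreement between observed and predicted
  scores are wide, and the source analysis reached the same conclusion.
* Exact numerical agreement with the original software's fits is not
  claimable: the original may use Gauss–Hermite quadrature and different
  M-step internals, and its fitted item parameters are not available for
  comparison.
* Graded-response/nominal models, DIF analysis, multiple imputation and
  equipercentile linking are out of scope.

## A worked run

```{r example, eval = FALSE}
# calibration-like cohort, Rasch crosswalk, both directions
dat <- simulate_pf10_haq(sim_config(n = 1791, seed = 2026))
lr <- build_crosswalk(dat$pf10, dat$haq_items, dat$aid_flags,
                      model = "PCM", method = "SDI")
lr$crosswalk
apply_crosswalk(lr$crosswalk, 1.0, from = "haq")

# the published converter
cw <- published_crosswalk("SDI")
apply_crosswalk(cw, 1.000, from = "haq")   # PF-10 55 (norm-based 38.1)

# fit diagnostics on the joint calibration
rev <- reverse_pf10_items(dat$pf10)
cats <- score_haq_categories(dat$haq_items, dat$aid_flags, "SDI")
item_fit(cbind(rev, cats), lr$calibration$params)
```
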