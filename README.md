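# pfhaqlink

Linking the two most widely used self-reported physical-function instruments
in rheumatoid arthritis: the **SF-36 physical functioning scale (PF-10)** and
the **Health Assessment Questionnaire disability index (HAQ-DI)**.

The two scales are not directly comparable — the PF-10 sums ten 3-category
items to a 0–100 score (higher = better function, 21 attainable values), the
HAQ-DI averages eight category scores into a 0–3 index (higher = more
disability, 25 attainable values, with standard "SDI" scoring raising a
category for aids/devices use and alternative "ADI" scoring ignoring it).
`pfhaqlink` implements the item-response-theory linking pipeline that builds a
**crosswalk** (concordance table) between them, and ships the published RA
crosswalk as a working converter.

## What it does

All models are adjacent-category logit models for ordered polytomous items:
with categories *k* = 0, …, *m*−1, discrimination *a* and thresholds *b₁, …,
b₍ₘ₋₁₎*,

> P(X = k | θ) ∝ exp( Σ₍h≤k₎ a (θ − b_h) ),

estimated by marginal maximum likelihood (EM over a fixed 61-node quadrature
grid, standard-normal prior). Three nested models are supported: the partial
credit model (PCM, all *a* = 1), the generalized partial credit model (GPCM),
and a between-item two-dimensional GPCM with estimated latent correlation ρ.
Crosswalks are built by co-calibrating the 10 reverse-coded PF-10 items with
the 8 HAQ category scores, computing sum-score → EAP tables per instrument via
the Lord–Wingersky recursion, and linking each attainable total score to the
score on the other instrument with the nearest EAP (ties toward better
function; extremes clip, never extrapolate).

Around that core:

* deterministic instrument scoring, including both HAQ-DI scoring rules and
  norm-based (T-metric) PF-10 scoring;
* item-fit diagnostics: observed vs expected mean item scores in low/average/
  high EAP groups, with the effect-size criterion ES < 0.10 (equivalently
  score-frequency differences of 2.5% / 3.33% for 4- / 3-category items);
* a validation battery: ICC(A,1) with F-based confidence intervals,
  Bland–Altman limits of agreement, DAS28 good-responder classification
  (improvement ≥ 1.2 and final ≤ 3.2), Cohen's d for change, and relative
  validity (ANOVA-F ratios) with BCa bootstrap intervals;
* a synthetic-data generator emulating the calibration (n = 1791) and
  cross-validation (n = 532/276) cohort structure, so the whole pipeline is
  testable without registry access;
* CSV round-trips for responses, item parameters and crosswalks, plus a thin
  command-line wrapper (`inst/cli/pfhaqlink.R`).

## Worked example

Convert scores through the packaged published crosswalk:

```r
library(pfhaqlink)

cw <- published_crosswalk("SDI")
apply_crosswalk(cw, 1.000, from = "haq")
#>   haq pf10 pf10_norm
#> 1   1   55      38.1
apply_crosswalk(cw, 80, from = "pf10")
#>   pf10 pf10_norm  haq
#> 1   80      48.6 0.25
```

A patient group averaging HAQ-SDI 1.0 corresponds to PF-10 55 (norm-based
38.1, about 1.2 SD below the general-population mean); an observed PF-10 of 80
converts to HAQ-SDI 0.25. Conversions are for group-level comparison, not
individual substitution.

Build a crosswalk from (here: simulated) item data and check it:

```r
dat <- simulate_pf10_haq(sim_config(n = 1791, seed = 2026))
lr <- build_crosswalk(dat$pf10, dat$haq_items, dat$aid_flags,
                      model = "PCM", method = "SDI")
lr$calibration
#> Calibration (PCM): 18 items, n = 1791
#> log-likelihood -30262.73886, 40 EM iterations
head(lr$crosswalk$haq_to_pf10, 5)
#>     haq pf10 pf10_norm   eap_haq  eap_pf10
#> 1 0.000  100      57.0 -3.005492 -2.740163
#> 2 0.125  100      57.0 -2.707495 -2.740163
#> 3 0.250   95      54.9 -2.440108 -2.425829
#> 4 0.375   90      52.8 -2.196038 -2.144290
#> 5 0.500   85      50.7 -1.969908 -1.887124
```

Each row pairs an observed HAQ-DI score with the PF-10 score whose sum-score
EAP is nearest on the common latent (disability) scale; the two EAP columns
show the matched locations. Within-sample agreement between observed and
crosswalk-predicted scores:

```r
sc <- score_sample(dat$pf10, dat$haq_items, dat$aid_flags)
icc_a1(sc$haq_sdi, apply_crosswalk(lr$crosswalk, sc$pf10_raw, from = "pf10")$haq)
#> ICC(A,1) = 0.820 (95% CI 0.804 to 0.834), n = 1791 -- adequate for group-level comparisons (>= 0.70)
```

See `vignettes/linking-methods.Rmd` for the model details, estimation
settings, design choices and the generator's assumptions.

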