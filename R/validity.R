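#' DAS28 good-responder classification
#'
#' EULAR-style good response at follow-up: the DAS28 improved by at least 1.2
#' points and the final score is at most 3.2. Anything else (including
#' moderate response) is `"non_or_moderate"`. Pairs with a missing value are
#' returned as `NA` (unclassified) with a message.
#'
#' @param das28_baseline,das28_followup DAS28 values at the two time points
#'   (plausible range 0-10).
#' @param improvement minimum improvement for a good response (default 1.2).
#' @param final_max maximum final score for a good response (default 3.2).
#' @return factor with levels `good`, `non_or_moderate` (`NA` = unclassified).
#' @examples
#' classify_responder(5.0, 3.0)  # good
#' classify_responder(4.0, 3.0)  # non_or_moderate: improvement only 1.0
#' classify_responder(6.0, 3.4)  # non_or_moderate: final score above 3.2
#' @export
classify_responder <- function(das28_baseline, das28_followup,
                               improvement = 1.2, final_max = 3.2) {
  if (length(das28_baseline) != length(das28_followup))
    stop("baseline and follow-up vectors must have equal length")
  rng <- range(c(das28_baseline, das28_followup), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 10)
    stop("DAS28 values outside the plausible range [0, 10]")
  miss <- is.na(das28_baseline) | is.na(das28_followup)
  if (any(miss))
    message(sum(miss), " pair(s) with missing DAS28 left unclassified")
  good <- (das28_baseline - das28_followup >= improvement) &
    (das28_followup <= final_max)
  out <- ifelse(good, "good", "non_or_moderate")
  out[miss] <- NA
  factor(out, levels = c("good", "non_or_moderate"))
}

#' Standardized change (Cohen's d) between baseline and follow-up
#'
#' Total effect size of longitudinal change: mean change divided by the
#' baseline SD (the common responsiveness convention for patient-reported
#' outcomes; set `denominator = "change"` for the change-score SD). The sign
#' convention makes improvement positive: for scales where higher is better
#' (PF-10) the change is follow-up minus baseline, otherwise (HAQ-DI)
#' baseline minus follow-up.
#'
#' @param baseline,followup paired longitudinal score vectors.
#' @param higher_is_better direction of the scale (default `TRUE`).
#' @param denominator `"baseline"` (default) or `"change"`.
#' @return Cohen's d (scalar).
#' @export
effect_size_change <- function(baseline, followup, higher_is_better = TRUE,
                               denominator = c("baseline", "change")) {
  denominator <- match.arg(denominator)
  ok <- !(is.na(baseline) | is.na(followup))
  baseline <- baseline[ok]; followup <- followup[ok]
  change <- if (higher_is_better) followup - baseline else baseline - followup
  s <- if (denominator == "baseline") stats::sd(baseline) else stats::sd(change)
  if (!is.finite(s) || s <= 0) stop("zero or undefined denominator SD")
  mean(change) / s
}

# one-way ANOVA F for a numeric outcome over a (two-level) grouping
oneway_f <- function(y, g) {
  g <- as.integer(g)
  n <- length(y)
  means <- tapply(y, g, mean)
  counts <- tapply(y, g, length)
  grand <- mean(y)
  ssb <- sum(counts * (means - grand)^2)
  ssw <- sum((y - means[as.character(g)])^2)
  dfb <- length(means) - 1L
  dfw <- n - length(means)
  (ssb / dfb) / (ssw / dfw)
}

#' Relative validity of predicted change scores with a BCa bootstrap CI
#'
#' Quantifies how well crosswalk-predicted change scores discriminate between
#' treatment-response groups relative to observed change scores: one-way
#' ANOVA F statistics of change on responder group are computed for both
#' series and their ratio `RV = F_predicted / F_observed` is reported with a
#' 95% bias-corrected and accelerated (BCa) bootstrap confidence interval,
#' resampling persons with a fixed seed. Jackknife estimates supply the
#' acceleration constant. A bootstrap resample that leaves a group empty is
#' redrawn (the count of redraws is reported).
#'
#' @param changes_predicted,changes_observed paired change-score vectors.
#' @param groups responder factor (two levels, each with n >= 2).
#' @param B number of bootstrap resamples (default 2000).
#' @param seed integer seed for the resampling generator.
#' @param conf confidence level (default 0.95).
#' @return list of class `relative_validity`: `rv`, `ci`, `f_predicted`,
#'   `f_observed`, `B`, `seed`, `n_redraws`, `group_n`.
#' @export
relative_validity <- function(changes_predicted, changes_observed, groups,
                              B = 2000L, seed = 1L, conf = 0.95) {
  groups <- as.factor(groups)
  ok <- !(is.na(changes_predicted) | is.na(changes_observed) | is.na(groups))
  yp <- changes_predicted[ok]; yo <- changes_observed[ok]
  g <- droplevels(groups[ok])
  if (nlevels(g) != 2L) stop("exactly two responder groups are required")
  if (any(table(g) < 2L)) stop("each group needs at least 2 persons")
  n <- length(yp)
  rv_of <- function(idx) oneway_f(yp[idx], g[idx]) / oneway_f(yo[idx], g[idx])
  t0 <- rv_of(seq_len(n))
  rng <- local({
    set.seed(seed)
    function(k) sample.int(n, k, replace = TRUE)
  })
  boot <- numeric(B)
  n_redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- rng(n)
      if (all(table(g[idx]) >= 2L)) break
      n_redraws <- n_redraws + 1L
    }
    boot[b] <- rv_of(idx)
  }
  ci <- bca_interval(t0, boot, function(idx) rv_of(idx), n, conf)
  out <- list(rv = t0, ci = ci, f_predicted = oneway_f(yp, g),
              f_observed = oneway_f(yo, g), B = B, seed = seed,
              n_redraws = n_redraws, group_n = table(g))
  class(out) <- "relative_validity"
  out
}

# BCa interval: bias correction from the bootstrap distribution, acceleration
# from the jackknife of the statistic over persons.
bca_interval <- function(t0, boot, stat_of_idx, n, conf = 0.95) {
  alpha <- (1 - conf) / 2
  prop <- mean(boot < t0)
  if (prop <= 0 || prop >= 1) {
    # degenerate bootstrap distribution: fall back to percentile limits
    return(stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE))
  }
  z0 <- stats::qnorm(prop)
  jack <- vapply(seq_len(n), function(i) stat_of_idx(setdiff(seq_len(n), i)),
                 numeric(1))
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den > 0) num / den else 0
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  probs <- c(adj(stats::qnorm(alpha)), adj(stats::qnorm(1 - alpha)))
  stats::quantile(boot, probs, names = FALSE)
}

#' @export
print.relative_validity <- function(x, ...) {
  cat(sprintf(
    "Relative validity: F_predicted = %.2f, F_observed = %.2f, RV = %.2f (95%% BCa CI %.2f to %.2f)\n  B = %d bootstrap resamples, seed %d%s\n",
    x$f_predicted, x$f_observed, x$rv, x$ci[1], x$ci[2], x$B, x$seed,
    if (x$n_redraws > 0) paste0(", ", x$n_redraws, " redraw(s)") else ""))
  invisible(x)
}

#' Longitudinal validity report for a crosswalk
#'
#' Builds the full responsiveness comparison for one measure: total effect
#' size (Cohen's d), mean (SD) change per responder group, ANOVA F, and, for
#' predicted series, the relative validity against the observed series with
#' its BCa bootstrap CI.
#'
#' @param observed_baseline,observed_followup observed scores at both time
#'   points.
#' @param predicted_baseline,predicted_followup crosswalk-predicted scores at
#'   both time points.
#' @param groups responder factor from [classify_responder()].
#' @param higher_is_better scale direction (see [effect_size_change()]).
#' @param B,seed bootstrap settings for [relative_validity()].
#' @return data.frame with rows `observed` and `predicted`: columns `es`,
#'   per-group mean and SD change, `f`, `rv`, `rv_lower`, `rv_upper`.
#' @export
validity_report <- function(observed_baseline, observed_followup,
                            predicted_baseline, predicted_followup,
                            groups, higher_is_better = TRUE,
                            B = 2000L, seed = 1L) {
  ok <- stats::complete.cases(observed_baseline, observed_followup,
                              predicted_baseline, predicted_followup, groups)
  ob <- observed_baseline[ok]; of <- observed_followup[ok]
  pb <- predicted_baseline[ok]; pf <- predicted_followup[ok]
  g <- droplevels(as.factor(groups[ok]))
  ch_o <- of - ob; ch_p <- pf - pb
  rv <- relative_validity(ch_p, ch_o, g, B = B, seed = seed)
  row <- function(base, fup, ch, f, rv_est, rv_ci) {
    out <- data.frame(
      es = effect_size_change(base, fup, higher_is_better),
      f = f, rv = rv_est, rv_lower = rv_ci[1], rv_upper = rv_ci[2])
    for (lev in levels(g)) {
      out[[paste0("change_mean_", lev)]] <- mean(ch[g == lev])
      out[[paste0("change_sd_", lev)]] <- stats::sd(ch[g == lev])
    }
    out
  }
  out <- rbind(
    observed = row(ob, of, ch_o, rv$f_observed, 1, c(NA, NA)),
    predicted = row(pb, pf, ch_p, rv$f_predicted, rv$rv, rv$ci))
  attr(out, "group_n") <- table(g)
  attr(out, "seed") <- seed
  out
}
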