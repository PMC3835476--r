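test_that("ICC(A,1) matches the mean-squares formula assembled from aov", {
  # 6-pair hand dataset
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  got <- icc_a1(x, y)
  # independent route: two-way ANOVA mean squares from stats::aov
  n <- length(x); k <- 2
  long <- data.frame(score = c(x, y),
                     subject = factor(rep(seq_len(n), k)),
                     rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  manual <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(got$icc, manual, tolerance = 1e-10)
  expect_equal(unname(got$ms), c(msr, msc, mse), tolerance = 1e-10)
})

test_that("ICC(A,1) behaves as an absolute-agreement statistic", {
  set.seed(91)
  x <- rnorm(80)
  expect_equal(icc_a1(x, x)$icc, 1)
  # symmetric in its arguments
  y <- x + rnorm(80, sd = 0.5)
  expect_equal(icc_a1(x, y)$icc, icc_a1(y, x)$icc, tolerance = 1e-12)
  # a constant offset is penalised relative to consistency-type correlation
  y2 <- x + 2
  expect_lt(icc_a1(x, y2)$icc, cor(x, y2))
  # joint rescaling of both raters leaves A,1 unchanged; rescaling one does not
  expect_equal(icc_a1(3 * x + 1, 3 * y + 1)$icc, icc_a1(x, y)$icc,
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(icc_a1(x, 3 * y)$icc, icc_a1(x, y)$icc)))
  # CI brackets the estimate; threshold flag fires at 0.70
  got <- icc_a1(x, y)
  expect_lt(got$ci[1], got$icc)
  expect_gt(got$ci[2], got$icc)
  expect_true(got$adequate_group_level == (got$icc >= 0.70))
  expect_error(icc_a1(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(icc_a1(1:2, 1:2), "at least 3")
})

test_that("Bland-Altman statistics match direct arithmetic", {
  # 5-pair hand dataset
  obs <- c(1.0, 2.0, 0.5, 3.0, 1.5)
  pred <- c(1.2, 1.7, 0.9, 2.5, 1.5)
  ba <- bland_altman(obs, pred)
  d <- obs - pred
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$sd_diff, sd(d))
  expect_equal(unname(ba$loa), mean(d) + c(-1.96, 1.96) * sd(d))
  expect_equal(ba$data$mean, (obs + pred) / 2)
  # LOA bracket the mean difference
  expect_lt(ba$loa[1], ba$mean_diff)
  expect_gt(ba$loa[2], ba$mean_diff)
  # observed-minus-predicted convention: y = x + c gives mean difference -c
  ba2 <- bland_altman(obs, obs + 3)
  expect_equal(ba2$mean_diff, -3)
  expect_equal(ba2$sd_diff, 0)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("the DAS28 responder rule requires both improvement and low final score", {
  expect_equal(as.character(classify_responder(5.0, 3.0)), "good")
  expect_equal(as.character(classify_responder(4.0, 3.0)), "non_or_moderate")
  expect_equal(as.character(classify_responder(6.0, 3.4)), "non_or_moderate")
  # boundary cases: exactly 1.2 improvement and exactly 3.2 final are good
  expect_equal(as.character(classify_responder(4.4, 3.2)), "good")
  # monotone: lowering follow-up never demotes a good responder
  base <- 5.0
  for (f1 in seq(3.2, 0.2, by = -0.2)) {
    expect_equal(as.character(classify_responder(base, f1)), "good")
  }
  # missing values are left unclassified with a message
  expect_message(out <- classify_responder(c(5, NA), c(3, 3)), "unclassified")
  expect_true(is.na(out[2]))
  expect_error(classify_responder(12, 3), "plausible range")
})

test_that("Cohen's d follows the baseline-SD convention with improvement positive", {
  set.seed(101)
  base <- rnorm(100, 50, 10)
  expect_equal(effect_size_change(base, base), 0)
  # uniform improvement of one baseline SD
  up <- base + sd(base)
  expect_equal(effect_size_change(base, up, higher_is_better = TRUE), 1)
  # for a disability scale, improvement means the score falls
  down <- base - sd(base)
  expect_equal(effect_size_change(base, down, higher_is_better = FALSE), 1)
  # change-SD denominator option
  fup <- base + 2 + rnorm(100)
  d_chg <- effect_size_change(base, fup, denominator = "change")
  expect_equal(d_chg, mean(fup - base) / sd(fup - base))
  expect_error(effect_size_change(rep(1, 10), rep(2, 10)), "zero")
})

test_that("relative validity is 1 with an exact CI when predicted equals observed", {
  set.seed(111)
  g <- factor(rep(c("good", "non_or_moderate"), each = 30))
  ch <- rnorm(60) + (as.integer(g) - 1)
  rv <- relative_validity(ch, ch, g, B = 200, seed = 7)
  expect_equal(rv$rv, 1)
  expect_lte(rv$ci[1], 1)
  expect_gte(rv$ci[2], 1)
  expect_equal(rv$f_predicted, rv$f_observed)
  # the F statistic matches stats::aov
  f_aov <- summary(stats::aov(ch ~ g))[[1]][1, "F value"]
  expect_equal(rv$f_observed, f_aov, tolerance = 1e-10)
})

test_that("bootstrap CIs are seed-reproducible and respond to real differences", {
  set.seed(121)
  g <- factor(rep(c("good", "non_or_moderate"), each = 40))
  eff <- ifelse(g == "good", 1.2, 0)
  obs <- eff + rnorm(80, sd = 1)
  pred <- 0.7 * eff + rnorm(80, sd = 1)
  rv1 <- relative_validity(pred, obs, g, B = 300, seed = 5)
  rv2 <- relative_validity(pred, obs, g, B = 300, seed = 5)
  expect_identical(rv1$ci, rv2$ci)
  expect_identical(rv1$rv, rv2$rv)
  rv3 <- relative_validity(pred, obs, g, B = 300, seed = 6)
  expect_false(identical(rv3$ci, rv1$ci))
  expect_error(relative_validity(pred, obs, factor(rep("a", 80)), B = 10),
               "two responder groups")
})

test_that("the BCa interval reduces to percentile limits when z0 = a = 0", {
  # a symmetric bootstrap distribution centred on t0 with a symmetric
  # jackknife: bias correction and acceleration both vanish
  t0 <- 0
  boot <- c(seq(-1, -0.001, length.out = 1000),
            seq(0.001, 1, length.out = 1000))  # exactly half below t0 -> z0 = 0
  sym_jack <- function(idx) 0  # constant jackknife -> a = 0
  ci <- pfhaqlink:::bca_interval(t0, boot, sym_jack, n = 10, conf = 0.95)
  expect_equal(ci, quantile(boot, c(0.025, 0.975), names = FALSE),
               tolerance = 1e-10)
})

test_that("shuffled group labels give F statistics near 1 on average", {
  set.seed(131)
  f_null <- replicate(200, {
    y <- rnorm(60)
    g <- sample(rep(1:2, each = 30))
    pfhaqlink:::oneway_f(y, g)
  })
  expect_equal(mean(f_null), 1, tolerance = 0.25)
})

test_that("the validity report assembles both series with group breakdowns", {
  set.seed(141)
  n <- 80
  g <- factor(rep(c("good", "non_or_moderate"), each = n / 2))
  ob <- rnorm(n, 1, 0.5)
  of <- ob - ifelse(g == "good", 0.6, 0.1) + rnorm(n, sd = 0.2)
  pb <- ob + rnorm(n, sd = 0.2)
  pf <- of + rnorm(n, sd = 0.2)
  vr <- validity_report(ob, of, pb, pf, g, higher_is_better = FALSE,
                        B = 100, seed = 3)
  expect_equal(rownames(vr), c("observed", "predicted"))
  expect_true(all(c("es", "f", "rv", "change_mean_good",
                    "change_sd_non_or_moderate") %in% names(vr)))
  expect_equal(vr["observed", "rv"], 1)
  expect_gt(vr["observed", "es"], 0)
})
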