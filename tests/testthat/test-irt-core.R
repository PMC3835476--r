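test_that("category probabilities follow the adjacent-category logit model", {
  # 2-category item at its threshold: both categories equally likely
  p <- category_probabilities(0.7, b = 0.7)
  expect_equal(as.vector(p), c(0.5, 0.5))
  # hand evaluation: unnormalised terms 1, e^1, e^0 at theta = 0, b = (-1, 1)
  p <- category_probabilities(0, b = c(-1, 1))
  expect_equal(as.vector(p), c(1, exp(1), 1) / (2 + exp(1)), tolerance = 1e-12)
  expect_equal(round(as.vector(p), 3), c(0.212, 0.576, 0.212))
  # normalisation for arbitrary items and thetas
  set.seed(21)
  for (i in 1:20) {
    m <- sample(2:5, 1)
    p <- category_probabilities(rnorm(7, sd = 2), b = sort(rnorm(m - 1)),
                                a = runif(1, 0.3, 2.5))
    expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-12)
    expect_true(all(p > 0))
  }
  expect_error(category_probabilities(Inf, b = 0), "finite")
})

test_that("quadrature weights are proper and the 2-D grid matches the prior", {
  g <- quad_grid()
  expect_length(g$nodes, 61)
  expect_equal(sum(g$weights), 1, tolerance = 1e-10)
  W <- quad_weights_2d(g$nodes, 0.73)
  expect_equal(sum(W), 1, tolerance = 1e-10)
  # rho = 0 factorises into the product of the marginal weights
  W0 <- quad_weights_2d(g$nodes, 0)
  expect_equal(W0, outer(g$weights, g$weights), tolerance = 1e-12)
  # grid correlation approximates rho
  rho_grid <- sum(W * outer(g$nodes, g$nodes)) /
    sqrt(sum(rowSums(W) * g$nodes^2) * sum(colSums(W) * g$nodes^2))
  expect_equal(rho_grid, 0.73, tolerance = 1e-3)
  expect_error(quad_weights_2d(g$nodes, 1), "rho")
})

test_that("pattern EAPs match brute-force integration on a 10x finer grid", {
  toy <- toy_params()
  fine <- quad_grid(610)
  for (pat in list(c(0, 0, 0), c(1, 1, 1), c(2, 2, 3), c(2, 0, 3), c(0, 2, 1))) {
    got <- eap_pattern(pat, toy)
    lik <- rep(1, 610)
    for (j in 1:3) {
      lik <- lik * category_probabilities(fine$nodes, thresholds(toy, j),
                                          toy$a[j])[, pat[j] + 1L]
    }
    f <- lik * fine$weights
    expect_equal(got$eap, sum(fine$nodes * f) / sum(f), tolerance = 1e-6)
    expect_equal(got$psd,
                 sqrt(sum(fine$nodes^2 * f) / sum(f) -
                        (sum(fine$nodes * f) / sum(f))^2),
                 tolerance = 1e-6)
  }
})

test_that("pattern EAPs are monotone in disability and symmetric at the centre", {
  toy <- toy_params()
  best <- eap_pattern(c(0, 0, 0), toy)$eap
  worst <- eap_pattern(c(2, 2, 3), toy)$eap
  expect_lt(best, worst)
  # symmetric item set, middle pattern: EAP is exactly 0
  sym <- item_params(c("s1", "s2"), n_cat = c(3, 3),
                     b = list(c(-1, 1), c(-1, 1)))
  expect_equal(eap_pattern(c(1, 1), sym)$eap, 0, tolerance = 1e-8)
  # missing responses are skipped; all-missing errors
  expect_silent(eap_pattern(c(NA, 1, 2), toy))
  expect_error(eap_pattern(c(NA, NA, NA), toy), "all-missing")
})

test_that("sum-score recursion equals exhaustive pattern enumeration", {
  toy <- toy_params()
  g <- quad_grid()
  F <- sum_score_posterior(toy, g)
  expect_equal(max(abs(F - enumerate_sum_scores(toy, g))), 0, tolerance = 1e-10)
  # conservation: total mass 1 at every node
  expect_equal(rowSums(F), rep(1, 61), tolerance = 1e-10)
  # single item: recursion returns the item's category probabilities
  one <- item_params("solo", 4L, b = list(c(-1, 0, 1)))
  expect_equal(unname(sum_score_posterior(one, g)),
               unname(category_probabilities(g$nodes, c(-1, 0, 1))))
})

test_that("sum-score EAP tables are monotone and match pattern EAPs under the PCM", {
  toy <- toy_params()
  g <- quad_grid()
  tab <- sum_score_eap_table(toy, g)
  expect_equal(nrow(tab), sum(toy$n_cat - 1L) + 1L)
  expect_true(all(diff(tab$eap) > 0))
  # Rasch sufficiency: any pattern with the same sum has the same EAP
  for (pat in list(c(2, 0, 3), c(1, 1, 3), c(2, 2, 1), c(0, 1, 0))) {
    expect_equal(tab$eap[tab$sum_score == sum(pat)],
                 eap_pattern(pat, toy)$eap, tolerance = 1e-6)
  }
  # extreme scores map to the extreme EAPs
  expect_equal(which.min(tab$eap), 1L)
  expect_equal(which.max(tab$eap), nrow(tab))
})

test_that("test information is additive, non-negative and translation-equivariant", {
  # single 2-category item at its threshold: Bernoulli variance 0.25
  one <- item_params("i", 2L, b = list(0.3))
  ti <- test_information(one, theta = 0.3)
  expect_equal(ti$total, 0.25)
  toy <- toy_params()
  ti <- test_information(toy)
  expect_true(all(ti$total >= 0))
  expect_equal(ti$total, rowSums(ti[, toy$item]))
  # shifting all thresholds by delta shifts the curve by delta
  delta <- 0.8
  shifted <- toy
  bcols <- grep("^b[0-9]+$", names(shifted))
  shifted[, bcols] <- shifted[, bcols] + delta
  t1 <- test_information(toy, theta = seq(-2, 2, 0.5))
  t2 <- test_information(shifted, theta = seq(-2, 2, 0.5) + delta)
  expect_equal(t1$total, t2$total, tolerance = 1e-10)
})

test_that("EM recovers a small PCM and keeps the log-likelihood monotone", {
  par <- default_item_params("PCM")
  th <- simulate_thetas(1500, seed = 31)
  x <- simulate_item_responses(th, par, seed = 32)
  fit <- fit_calibration(x, "PCM")
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  bt <- unlist(thresholds(par)); be <- unlist(thresholds(fit$params))
  expect_gt(cor(bt, be), 0.99)
  expect_true(all(fit$params$a == 1))
  # GPCM on the same data: discriminations near 1, likelihood no worse
  fitg <- fit_calibration(x, "GPCM")
  expect_lt(mean(abs(fitg$params$a - 1)), 0.1)
  expect_gte(fitg$loglik, fit$loglik)
})

test_that("unobserved categories collapse by default and error in strict mode", {
  par <- item_params(c("i1", "i2", "i3"), n_cat = c(3, 3, 3),
                     b = list(c(-1, 1), c(-0.5, 0.5), c(0, 1)))
  th <- simulate_thetas(400, seed = 41)
  x <- simulate_item_responses(th, par, seed = 42)
  x[x[, 1] == 2, 1] <- 1L  # top category of item 1 never observed
  expect_error(fit_calibration(x, "PCM", n_cat = c(3, 3, 3),
                               unobserved = "error"),
               "unobserved")
  expect_warning(fit <- fit_calibration(x, "PCM", n_cat = c(3, 3, 3)),
                 "collapsing")
  expect_equal(fit$params$n_cat[1], 2L)
  expect_named(fit$collapsed, "i1")
})

test_that("calibration input validation catches degenerate inputs", {
  x <- matrix(c(0L, 1L), nrow = 1)
  expect_error(fit_calibration(x, "PCM"), "at least 2 persons")
  x2 <- matrix(rep(c(0L, 0L, 1L, 1L), 50), ncol = 2)
  expect_error(suppressWarnings(
    fit_calibration(cbind(x2, 0L), "PCM")), "fewer than 2")
  expect_error(fit_calibration(x2, "MIRT2"), "dims")
  expect_error(fit_calibration(x2, "MIRT2", dims = c(1, 1)),
               "both dimensions")
})
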