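test_that("co-calibration validates its inputs and yields 18 joint items", {
  dat <- sim_cohort()
  rev <- reverse_pf10_items(dat$pf10)
  cats <- score_haq_categories(dat$haq_items, dat$aid_flags, "SDI")
  expect_error(co_calibrate(rev[-1, ], cats), "person-set mismatch")
  expect_error(co_calibrate(rev[, -1], cats), "10")
  expect_error(co_calibrate(rev + 5L, cats), "\\{0, 1, 2\\}")
  fit <- cached("joint_pcm_600", co_calibrate(rev, cats, "PCM"))
  expect_equal(nrow(fit$params), 18L)
  expect_equal(fit$params$n_cat, c(rep(3L, 10), rep(4L, 8)))
})

test_that("instrument score tables have 21 and 25 rows and are monotone", {
  dat <- sim_cohort()
  rev <- reverse_pf10_items(dat$pf10)
  cats <- score_haq_categories(dat$haq_items, dat$aid_flags, "SDI")
  fit <- cached("joint_pcm_600", co_calibrate(rev, cats, "PCM"))
  tabs <- instrument_score_tables(fit)
  expect_equal(nrow(tabs$pf10), 21L)
  expect_equal(nrow(tabs$haq), 25L)
  expect_true(all(diff(tabs$pf10$eap) > 0))
  expect_true(all(diff(tabs$haq$eap) > 0))
})

test_that("nearest-EAP linking matches the exhaustive-search oracle", {
  dat <- sim_cohort()
  rev <- reverse_pf10_items(dat$pf10)
  cats <- score_haq_categories(dat$haq_items, dat$aid_flags, "SDI")
  fit <- cached("joint_pcm_600", co_calibrate(rev, cats, "PCM"))
  tabs <- instrument_score_tables(fit)
  link <- nearest_link(tabs$haq, tabs$pf10)
  for (i in seq_len(nrow(tabs$haq))) {
    d <- abs(tabs$haq$eap[i] - tabs$pf10$eap)
    expect_equal(link$score_b[i], tabs$pf10$sum_score[which(d == min(d))[1]])
  }
  # identity map when both tables coincide
  self <- nearest_link(tabs$pf10, tabs$pf10)
  expect_equal(self$score_b, self$score_a)
  # monotone non-decreasing in the disability direction
  expect_true(all(diff(link$score_b) >= 0))
  expect_error(nearest_link(tabs$pf10[0, ], tabs$haq), "empty")
})

test_that("nearest-EAP ties break toward better function", {
  ta <- structure(data.frame(sum_score = 0:1, eap = c(0, 1), psd = 1),
                  class = c("score_table", "data.frame"))
  tb <- structure(data.frame(sum_score = 0:2, eap = c(-0.5, 0.5, 1.5), psd = 1),
                  class = c("score_table", "data.frame"))
  # eap 0 is equidistant from -0.5 and 0.5; eap 1 equidistant from 0.5 and 1.5
  link <- nearest_link(ta, tb)
  expect_equal(link$score_b, c(0L, 1L))
})

test_that("built crosswalks are total, monotone, clipped, and deterministic", {
  dat <- sim_cohort()
  lr <- cached("link_pcm_600",
               build_crosswalk(dat$pf10, dat$haq_items, dat$aid_flags,
                               model = "PCM", method = "SDI"))
  cw <- lr$crosswalk
  expect_s3_class(cw, "crosswalk")
  expect_equal(sort(cw$haq_to_pf10$haq), attainable_scores("HAQ_SDI"))
  expect_equal(sort(cw$pf10_to_haq$pf10), sort(attainable_scores("PF10_RAW")))
  expect_true(all(cw$haq_to_pf10$pf10 %in% attainable_scores("PF10_RAW")))
  expect_true(all(cw$pf10_to_haq$haq %in% attainable_scores("HAQ_SDI")))
  # deterministic: rebuilding from the same responses gives identical tables
  lr2 <- build_crosswalk(dat$pf10, dat$haq_items, dat$aid_flags,
                         model = "PCM", method = "SDI")
  expect_identical(lr2$crosswalk$haq_to_pf10, cw$haq_to_pf10)
  expect_identical(lr2$crosswalk$pf10_to_haq, cw$pf10_to_haq)
})

test_that("round trips through a built crosswalk move scores at most two steps", {
  dat <- sim_cohort()
  lr <- cached("link_pcm_600",
               build_crosswalk(dat$pf10, dat$haq_items, dat$aid_flags,
                               model = "PCM", method = "SDI"))
  cw <- lr$crosswalk
  for (h in attainable_scores("HAQ_SDI")) {
    p <- apply_crosswalk(cw, h, from = "haq")$pf10
    back <- apply_crosswalk(cw, p, from = "pf10")$haq
    expect_lte(abs(back - h), 2 * 0.125)
  }
  for (p in attainable_scores("PF10_RAW")) {
    h <- apply_crosswalk(cw, p, from = "pf10")$haq
    back <- apply_crosswalk(cw, h, from = "haq")$pf10
    expect_lte(abs(back - p), 2 * 5)
  }
})

test_that("SDI predictions indicate at least as much disability as ADI", {
  dat <- sim_cohort()
  lr_sdi <- cached("link_pcm_600",
                   build_crosswalk(dat$pf10, dat$haq_items, dat$aid_flags,
                                   model = "PCM", method = "SDI"))
  lr_adi <- cached("link_pcm_600_adi",
                   build_crosswalk(dat$pf10, dat$haq_items, dat$aid_flags,
                                   model = "PCM", method = "ADI"))
  sdi_pred <- lr_sdi$crosswalk$pf10_to_haq
  adi_pred <- lr_adi$crosswalk$pf10_to_haq
  expect_equal(sdi_pred$pf10, adi_pred$pf10)
  expect_true(all(sdi_pred$haq >= adi_pred$haq))
  # and on the published tables
  pub_s <- published_crosswalk("SDI")$pf10_to_haq
  pub_a <- published_crosswalk("ADI")$pf10_to_haq
  expect_true(all(pub_s$haq >= pub_a$haq))
})

test_that("score conversion errors on unattainable values with a suggestion", {
  cw <- published_crosswalk("SDI")
  expect_error(apply_crosswalk(cw, 42, from = "pf10"), "nearest attainable.*40")
  expect_error(apply_crosswalk(cw, 1.3, from = "haq"), "nearest attainable")
  expect_equal(apply_crosswalk(cw, c(0, 3), from = "haq")$pf10, c(95, 0))
})

test_that("crosswalk CSV serialisation round-trips bit-exactly", {
  dat <- sim_cohort()
  lr <- cached("link_pcm_600",
               build_crosswalk(dat$pf10, dat$haq_items, dat$aid_flags,
                               model = "PCM", method = "SDI"))
  path <- tempfile(fileext = ".csv")
  write_crosswalk(lr$crosswalk, path)
  back <- read_crosswalk(path)
  expect_identical(back$haq_to_pf10$haq, lr$crosswalk$haq_to_pf10$haq)
  expect_identical(back$haq_to_pf10$pf10, lr$crosswalk$haq_to_pf10$pf10)
  expect_identical(back$pf10_to_haq$haq, lr$crosswalk$pf10_to_haq$haq)
  expect_identical(back$method, "SDI")
  # writing the read-back object reproduces the file byte for byte
  path2 <- tempfile(fileext = ".csv")
  write_crosswalk(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the crosswalk constructor enforces totality and monotonicity", {
  pub <- published_table("SDI")
  h2p <- pub$haq_to_pf10; h2p$pf10_norm <- pf10_norm_based(h2p$pf10)
  p2h <- pub$pf10_to_haq; p2h$pf10_norm <- pf10_norm_based(p2h$pf10)
  expect_s3_class(new_crosswalk(h2p, p2h, "SDI"), "crosswalk")
  expect_error(new_crosswalk(h2p[-1, ], p2h, "SDI"), "25")
  broken <- h2p; broken$pf10[3] <- 100  # worse HAQ maps to better PF-10
  expect_error(new_crosswalk(broken, p2h, "SDI"), "monotone")
  off_grid <- h2p; off_grid$pf10[3] <- 42
  expect_error(new_crosswalk(off_grid, p2h, "SDI"), "attainable")
})
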