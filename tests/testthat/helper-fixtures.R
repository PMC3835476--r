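# Shared lazy fixtures: expensive objects built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small 3-item toy instrument (mixed 3- and 4-category) used by the
# enumeration and fine-grid oracles
toy_params <- function() {
  item_params(c("t1", "t2", "t3"), n_cat = c(3L, 3L, 4L),
              b = list(c(-1, 0.5), c(-0.2, 1.2), c(-1.5, 0, 1)))
}

# brute-force sum-score distribution by exhaustive pattern enumeration
enumerate_sum_scores <- function(params, grid) {
  cats <- lapply(params$n_cat, function(m) 0:(m - 1L))
  pats <- as.matrix(expand.grid(cats))
  smax <- sum(params$n_cat - 1L)
  out <- matrix(0, length(grid$nodes), smax + 1L)
  for (i in seq_len(nrow(pats))) {
    p <- rep(1, length(grid$nodes))
    for (j in seq_len(nrow(params))) {
      p <- p * category_probabilities(grid$nodes, thresholds(params, j),
                                      params$a[j])[, pats[i, j] + 1L]
    }
    s <- sum(pats[i, ])
    out[, s + 1L] <- out[, s + 1L] + p
  }
  out
}

# a moderately sized unidimensional cohort shared across linking tests
sim_cohort <- function(n = 600L, seed = 101L) {
  cached(paste0("cohort_", n, "_", seed), {
    simulate_pf10_haq(sim_config(n = n, seed = seed))
  })
}

# published Table-2 values, transcribed independently of the packaged CSVs:
# used to check the fixture + converter reproduce the publication exactly
published_table <- function(method) {
  haq <- seq(0, 3, by = 0.125)
  pf_desc <- seq(100, 0, by = -5)
  if (method == "SDI") {
    list(
      haq_to_pf10 = data.frame(haq = haq, pf10 = c(
        95, 90, 85, 75, 75, 70, 65, 60, 55, 50, 45, 45, 40,
        35, 30, 25, 20, 20, 15, 10, 5, 5, 0, 0, 0)),
      pf10_to_haq = data.frame(pf10 = pf_desc, haq = c(
        0.000, 0.000, 0.125, 0.250, 0.250, 0.375, 0.625, 0.750, 0.875,
        1.000, 1.125, 1.375, 1.500, 1.625, 1.750, 1.875, 2.125, 2.250,
        2.375, 2.625, 2.750)))
  } else {
    list(
      haq_to_pf10 = data.frame(haq = haq, pf10 = c(
        95, 85, 80, 75, 70, 65, 55, 50, 45, 45, 40, 35, 30,
        25, 25, 25, 20, 15, 10, 10, 5, 5, 0, 0, 0)),
      pf10_to_haq = data.frame(pf10 = pf_desc, haq = c(
        0.000, 0.000, 0.125, 0.125, 0.250, 0.375, 0.500, 0.625, 0.625,
        0.750, 1.000, 1.125, 1.250, 1.375, 1.500, 1.750, 2.000, 2.125,
        2.250, 2.625, 2.750)))
  }
}
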