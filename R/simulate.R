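#' Simulation configuration
#'
#' Bundles the generator settings that define a simulated cohort. Defaults
#' emulate the structure of the RA calibration study: n = 1791 persons with a
#' unidimensional latent disability; the cross-validation scenario uses
#' n = 532 at baseline (latent mean shifted -0.5, i.e. better function) with
#' a 276-person longitudinal block in which roughly 49% of patients
#' (134/276) are DAS28 good responders. Item thresholds follow a stylized
#' layout in which the PF-10 items target better levels of function and the
#' HAQ categories are shifted toward worse function.
#'
#' @param n number of persons.
#' @param model generating model (`"PCM"`, `"GPCM"` or `"MIRT2"`).
#' @param rho latent correlation between the PF-10 and HAQ dimensions under
#'   `"MIRT2"` (default 0.73).
#' @param scenario `"calibration"` (n = 1791, latent mean 0) or `"crossval"`
#'   (n = 532, latent mean -0.5).
#' @param theta_mean latent mean (overrides the scenario default).
#' @param n_longitudinal persons in the longitudinal block (crossval scenario).
#' @param good_fraction fraction of good responders (default 134/276).
#' @param improvement_good,improvement_other mean latent improvement (drop in
#'   disability) per responder group over 6 months.
#' @param change_sd SD of the person-level latent change noise.
#' @param aid_intercept,aid_slope per-category logistic model for aids/devices
#'   use: `P(flag) = plogis(aid_intercept + aid_slope * theta)`, so use
#'   increases with disability.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n = NULL, model = "PCM", rho = 0.73,
                       scenario = c("calibration", "crossval"),
                       theta_mean = NULL, n_longitudinal = 276L,
                       good_fraction = 134 / 276,
                       improvement_good = 0.9, improvement_other = 0.05,
                       change_sd = 0.3,
                       aid_intercept = -2, aid_slope = 1, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(n)) n <- if (scenario == "calibration") 1791L else 532L
  if (is.null(theta_mean)) theta_mean <- if (scenario == "calibration") 0 else -0.5
  stopifnot(n >= 1, abs(rho) < 1, good_fraction >= 0, good_fraction <= 1)
  structure(list(n = as.integer(n), model = model, rho = rho,
                 scenario = scenario, theta_mean = theta_mean,
                 n_longitudinal = as.integer(n_longitudinal),
                 good_fraction = good_fraction,
                 improvement_good = improvement_good,
                 improvement_other = improvement_other,
                 change_sd = change_sd, aid_intercept = aid_intercept,
                 aid_slope = aid_slope, seed = as.integer(seed)),
            class = "sim_config")
}

#' Stylized item parameters for the joint PF-10 / HAQ instrument
#'
#' Default generating parameters for simulation: 10 three-category PF-10
#' items with locations spread over the better-function range and 8
#' four-category HAQ category-score items shifted toward worse function
#' (mirroring the instruments' published targeting). Under `"GPCM"` the
#' discriminations vary around 1; under `"MIRT2"` the PF-10 items load on
#' dimension 1 and the HAQ categories on dimension 2.
#'
#' @param model `"PCM"`, `"GPCM"` or `"MIRT2"`.
#' @return an [item_params()] object with 18 items.
#' @export
default_item_params <- function(model = c("PCM", "GPCM", "MIRT2")) {
  model <- match.arg(model)
  pf_loc <- seq(-1.8, 0.9, length.out = 10)
  haq_loc <- seq(-0.9, 1.8, length.out = 8)
  b <- c(lapply(pf_loc, function(l) l + c(-0.7, 0.7)),
         lapply(haq_loc, function(l) l + c(-0.9, 0, 0.9)))
  a <- if (model == "PCM") rep(1, 18) else
    rep(c(0.8, 1.25, 1, 0.9, 1.1, 1.4), 3)
  dims <- if (model == "MIRT2") c(rep(1L, 10), rep(2L, 8)) else rep(1L, 18)
  item_params(c(pf10_items(), names(haq_categories())),
              n_cat = c(rep(3L, 10), rep(4L, 8)), b = b, a = a, dim = dims)
}

#' Simulate latent disability scores
#'
#' Standard-normal latent scores (plus `mean`); under a two-dimensional
#' configuration, a bivariate normal with standard margins and correlation
#' `rho` (dimension 1 = PF-10, dimension 2 = HAQ).
#'
#' @param n number of persons.
#' @param rho latent correlation; `NULL` for a unidimensional vector.
#' @param mean latent mean (scalar or per-dimension).
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return numeric vector (1-D) or an `n x 2` matrix.
#' @export
simulate_thetas <- function(n, rho = NULL, mean = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(rho)) return(stats::rnorm(n, mean = mean))
  stopifnot(abs(rho) < 1)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  mean <- rep_len(mean, 2L)
  cbind(mean[1] + z1, mean[2] + rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Simulate item responses from a (generalized) partial credit model
#'
#' Categorical draws from [category_probabilities()] at each person's latent
#' score, item by item.
#'
#' @param thetas latent scores: vector, or `n x 2` matrix for two-dimensional
#'   parameter sets (column `d` feeds the items with `dim == d`).
#' @param params an [item_params()] object.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return integer matrix, `n` rows, one column per item, categories
#'   `0 .. n_cat - 1`.
#' @export
simulate_item_responses <- function(thetas, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- if (is.matrix(thetas)) thetas else matrix(thetas, ncol = 1L)
  n <- nrow(th)
  out <- matrix(NA_integer_, n, nrow(params))
  colnames(out) <- params$item
  for (j in seq_len(nrow(params))) {
    d <- min(params$dim[j], ncol(th))
    P <- category_probabilities(th[, d], thresholds(params, j), params$a[j])
    cum <- t(apply(P, 1L, cumsum))
    cum[, ncol(cum)] <- 1
    u <- stats::runif(n)
    out[, j] <- max.col(u <= cum, ties.method = "first") - 1L
  }
  out
}

#' Simulate a full PF-10 + HAQ-DI cohort at the instrument level
#'
#' Generates what the scoring pipeline consumes: PF-10 responses in the
#' original 1-3 coding, the 20 HAQ items in 0-3, and the 8 per-category
#' aids/devices indicators drawn from a logistic model in latent disability
#' (so aid use rises with disability and SDI totals are never below ADI
#' totals). HAQ item responses are drawn per item with the item's thresholds
#' jittered around its category's location, then the category score is the
#' within-category maximum, as in real scoring.
#'
#' @param config a [sim_config()].
#' @param thetas optional latent scores (otherwise drawn per `config`).
#' @return list with `pf10` (n x 10, 1-3), `haq_items` (n x 20, 0-3),
#'   `aid_flags` (n x 8 logical), `theta`, and the `config`.
#' @export
simulate_pf10_haq <- function(config = sim_config(), thetas = NULL) {
  set.seed(config$seed)
  two_dim <- config$model == "MIRT2"
  if (is.null(thetas)) {
    thetas <- simulate_thetas(config$n, rho = if (two_dim) config$rho,
                              mean = config$theta_mean)
  }
  th <- if (is.matrix(thetas)) thetas else cbind(thetas, thetas)
  params <- default_item_params(config$model)
  pf_par <- params[params$item %in% pf10_items(), ]
  class(pf_par) <- c("item_params", "data.frame")
  pf_rev <- simulate_item_responses(th[, 1], pf_par)
  pf10 <- 3L - pf_rev  # back to the original 1-3 coding

  cats <- haq_categories()
  haq_par <- params[!params$item %in% pf10_items(), ]
  n_items <- length(unlist(cats))
  hmat <- matrix(NA_integer_, nrow(th), n_items)
  colnames(hmat) <- haq_items()
  col <- 0L
  for (ci in seq_along(cats)) {
    bc <- thresholds(haq_par, ci)
    for (k in seq_along(cats[[ci]])) {
      col <- col + 1L
      # within-category items: same location, small deterministic jitter
      bj <- bc + 0.2 * (k - (length(cats[[ci]]) + 1) / 2)
      pj <- item_params(colnames(hmat)[col], 4L, b = list(bj),
                        a = haq_par$a[ci])
      hmat[, col] <- simulate_item_responses(th[, 2], pj)
    }
  }
  aid_p <- stats::plogis(config$aid_intercept + config$aid_slope * th[, 2])
  aid_flags <- matrix(stats::runif(nrow(th) * 8) < aid_p, ncol = 8)
  colnames(aid_flags) <- names(cats)
  list(pf10 = pf10, haq_items = hmat, aid_flags = aid_flags,
       theta = thetas, config = config)
}

#' Simulate a longitudinal cross-validation cohort
#'
#' Baseline and 6-month instrument data with DAS28 pairs: responder labels
#' are drawn with the configured good-responder fraction; good responders
#' improve by `improvement_good` latent units on average (disability falls),
#' others by `improvement_other`; DAS28 pairs are generated so that the
#' labels match [classify_responder()] by construction.
#'
#' @param config a [sim_config()] (use `scenario = "crossval"`).
#' @return list with `baseline` and `followup` (each as returned by
#'   [simulate_pf10_haq()]), `das28` (data.frame `baseline`, `followup`),
#'   `group` (factor), and `config`.
#' @export
simulate_longitudinal <- function(config = sim_config(scenario = "crossval")) {
  set.seed(config$seed)
  n <- config$n_longitudinal
  th0 <- simulate_thetas(n, mean = config$theta_mean)
  good <- stats::runif(n) < config$good_fraction
  improvement <- ifelse(good, config$improvement_good, config$improvement_other)
  th1 <- th0 - improvement + stats::rnorm(n, sd = config$change_sd)
  das_b <- pmin(pmax(stats::rnorm(n, 4.3, 1.2), 1.6), 9.5)
  das_f <- numeric(n)
  # good responders: final <= 3.2 and improvement >= 1.2 by construction
  das_b[good] <- pmax(das_b[good], 2.0)
  das_f[good] <- pmin(das_b[good] - 1.2 - stats::rexp(sum(good), 2),
                      3.2 - stats::runif(sum(good), 0, 0.8))
  das_f[good] <- pmax(das_f[good], 0.3)
  # others: improvement below 1.2, or final above 3.2
  small_impr <- stats::runif(sum(!good), -0.5, 1.1)
  das_f[!good] <- das_b[!good] - small_impr
  viol <- !good & (das_b - das_f >= 1.2) & (das_f <= 3.2)
  das_f[viol] <- pmax(das_b[viol] - 1.1, 3.25)
  das_f <- pmin(pmax(das_f, 0.2), 9.8)

  cfg_b <- config; cfg_b$n <- n; cfg_b$seed <- config$seed + 1L
  cfg_f <- config; cfg_f$n <- n; cfg_f$seed <- config$seed + 2L
  base <- simulate_pf10_haq(cfg_b, thetas = th0)
  fup <- simulate_pf10_haq(cfg_f, thetas = th1)
  list(baseline = base, followup = fup,
       das28 = data.frame(baseline = das_b, followup = das_f),
       group = factor(ifelse(good, "good", "non_or_moderate"),
                      levels = c("good", "non_or_moderate")),
       config = config)
}
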