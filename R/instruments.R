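#' Instrument definitions for the PF-10 and HAQ-DI
#'
#' The PF-10 is the 10-item physical functioning scale of the SF-36: each item
#' is answered on a 3-point scale from 1 ("yes, limited a lot") to 3 ("no, not
#' limited at all"). The HAQ-DI contains 20 items in eight categories of daily
#' living, each scored 0 ("without any difficulty") to 3 ("unable to do"),
#' plus one aids/devices-or-help indicator per category.
#'
#' `haq_categories()` returns the standard item-to-category partition (the
#' 2/2/3/2/3/2/3/3 layout). `pf10_items()` returns the PF-10 item identifiers.
#'
#' @return `haq_categories()`: a named list of integer vectors of item column
#'   indices, one per category. `pf10_items()`: a character vector of length 10.
#' @export
haq_categories <- function() {
  list(
    dressing_grooming = 1:2,
    rising            = 3:4,
    eating            = 5:7,
    walking           = 8:9,
    hygiene           = 10:12,
    reach             = 13:14,
    grip              = 15:17,
    activities        = 18:20
  )
}

#' @rdname haq_categories
#' @export
pf10_items <- function() paste0("pf", sprintf("%02d", 1:10))

#' @rdname haq_categories
#' @export
haq_items <- function() {
  cats <- haq_categories()
  unlist(lapply(names(cats), function(nm) {
    paste0("haq_", nm, "_", seq_along(cats[[nm]]))
  }), use.names = FALSE)
}

check_pf10 <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 10L)
    stop("a PF-10 response has exactly 10 items, got ", length(items))
  bad <- which(!is.na(items) & !items %in% c(1, 2, 3))
  if (length(bad))
    stop("PF-10 item(s) ", paste(bad, collapse = ", "),
         " outside the response range {1, 2, 3}")
  items
}

#' Score the PF-10
#'
#' `score_pf10_raw()` computes the traditional 0-100 PF-10 score: the ten item
#' responses (1-3) are summed and linearly transformed, so the attainable raw
#' scores are 0, 5, ..., 100 with higher scores indicating better physical
#' function. `reverse_pf10_items()` recodes items to the disability direction
#' (0 = no limitation, 2 = limited a lot) used in IRT calibration, where a
#' higher latent score means worse function.
#'
#' @param items integer vector of length 10 with values in \{1, 2, 3\}; `NA`
#'   denotes a missing response. A matrix with 10 columns scores each row.
#' @return `score_pf10_raw()`: numeric raw score(s) in \{0, 5, ..., 100\}.
#'   `reverse_pf10_items()`: responses recoded to \{0, 1, 2\}, same shape as
#'   the input.
#' @examples
#' score_pf10_raw(rep(3, 10))   # 100, no limitations
#' score_pf10_raw(rep(1, 10))   # 0, limited a lot throughout
#' reverse_pf10_items(c(1, 2, 3, 3, 3, 2, 1, 2, 3, 1))
#' @export
score_pf10_raw <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    return(apply(as.matrix(items), 1L, score_pf10_raw))
  }
  items <- check_pf10(items)
  if (anyNA(items))
    stop("missing PF-10 item(s): ", paste(which(is.na(items)), collapse = ", "),
         " (complete-case scoring)")
  (sum(items) - 10) * 5  # = (sum - 10) / 20 * 100, exact on the 5-point grid
}

#' @rdname score_pf10_raw
#' @export
reverse_pf10_items <- function(items) {
  if (is.matrix(items) || is.data.frame(items)) {
    m <- as.matrix(items)
    out <- apply(m, 1L, function(r) 3 - check_pf10(r))
    return(t(out))
  }
  3 - check_pf10(items)
}

#' Norm-based scoring of the PF-10
#'
#' Transforms a 0-100 PF-10 raw score to the T-score metric with mean 50 and
#' standard deviation 10 in the 1998 US general population:
#' `50 + 10 * (raw - mu) / sigma`. The default coefficients were estimated by
#' least squares from the 21 published (raw, norm-based) score pairs, under
#' the constraint that every published norm-based value is reproduced to one
#' decimal (see `scripts/regenerate-norm-coefficients.R` in the source tree).
#'
#' @param raw PF-10 raw score(s) on the 0-100 metric.
#' @param coef a list with elements `mu` (reference mean of the raw score) and
#'   `sigma` (reference SD, > 0); defaults to [default_norm_coefficients()].
#' @param digits decimal places for the returned T-score (the published tables
#'   print one decimal); use `NA` for no rounding.
#' @return numeric norm-based score(s).
#' @examples
#' pf10_norm_based(0)    # 14.9
#' pf10_norm_based(100)  # 57.0
#' @export
pf10_norm_based <- function(raw, coef = default_norm_coefficients(), digits = 1) {
  if (!is.list(coef) || is.null(coef$mu) || is.null(coef$sigma))
    stop("`coef` must be a list with elements `mu` and `sigma`")
  if (!is.finite(coef$sigma) || coef$sigma <= 0)
    stop("invalid norm coefficients: `sigma` must be > 0")
  bad <- !is.na(raw) & !raw %in% attainable_scores("PF10_RAW")
  if (any(bad))
    stop("raw score(s) not attainable on the PF-10: ",
         paste(unique(raw[bad]), collapse = ", "))
  out <- 50 + 10 * (raw - coef$mu) / coef$sigma
  if (!is.na(digits)) out <- round(out, digits)
  out
}

#' Default PF-10 norm-based scoring coefficients
#'
#' Reference-population mean and SD of the 0-100 PF-10 raw score used by
#' [pf10_norm_based()]. Frozen constants; see
#' `scripts/regenerate-norm-coefficients.R` for how they are estimated from
#' the 21 published (raw, norm-based) pairs.
#'
#' @return list with elements `mu` and `sigma`.
#' @export
default_norm_coefficients <- function() {
  list(mu = 83.3082147333, sigma = 23.7656987442)
}

#' The published (raw, norm-based) PF-10 score pairs
#'
#' The 21 attainable PF-10 raw scores with their published norm-based
#' (T-metric) companions, used to estimate [default_norm_coefficients()].
#'
#' @return data.frame with columns `raw` and `norm`.
#' @keywords internal
#' @export
pf10_norm_pairs <- function() {
  data.frame(
    raw  = seq(0, 100, by = 5),
    norm = c(14.9, 17.0, 19.2, 21.3, 23.4, 25.5, 27.6, 29.7, 31.8, 33.9,
             36.0, 38.1, 40.2, 42.3, 44.4, 46.5, 48.6, 50.7, 52.8, 54.9, 57.0)
  )
}

#' Estimate norm-based scoring coefficients from printed score pairs
#'
#' Least-squares fit of `norm = 50 + 10 (raw - mu) / sigma` to printed
#' (raw, norm-based) pairs, penalised so that every printed value is
#' reproduced to one decimal (the printed column carries the reference
#' population's own rounding, which plain least squares does not honour).
#'
#' @param pairs data.frame with columns `raw` and `norm`; defaults to the
#'   published pairs from [pf10_norm_pairs()].
#' @return list with `mu` and `sigma` as in [default_norm_coefficients()].
#' @export
fit_norm_coefficients <- function(pairs = pf10_norm_pairs()) {
  ls0 <- stats::coef(stats::lm(norm ~ raw, data = pairs))
  obj <- function(p) {
    pred <- p[1] + p[2] * pairs$raw
    err <- pred - pairs$norm
    sum(err^2) + 1e6 * sum(pmax(abs(err) - 0.0499, 0)^2)
  }
  o <- stats::optim(unname(ls0), obj, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o <- stats::optim(o$par, obj, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-14))
  slope <- o$par[2]; intercept <- o$par[1]
  sigma <- 10 / slope
  list(mu = (50 - intercept) * sigma / 10, sigma = sigma)
}

#' Score the HAQ-DI
#'
#' `score_haq_categories()` reduces the 20 HAQ-DI items to the eight category
#' scores: each category's score is the highest item score within it, and,
#' under standard (SDI) scoring, is raised to 2 when aids/devices or help
#' from another person are used for that category and the item maximum is
#' below 2. Alternative (ADI) scoring ignores the aid indicators.
#' `score_haq_total()` averages the eight category scores, giving the 0-3
#' disability index in steps of 0.125.
#'
#' @param items integer vector of length 20 (values 0-3, `NA` = missing) or a
#'   matrix with 20 columns (one row per person).
#' @param aid_flags logical vector of length 8 (or matrix with 8 columns),
#'   one per category; ignored under `method = "ADI"`.
#' @param method `"SDI"` (standard, aids/devices adjustment) or `"ADI"`.
#' @param categories item-to-category partition, as [haq_categories()].
#' @param category_scores numeric vector of 8 category scores in 0-3 (or a
#'   matrix with 8 columns).
#' @param min_categories minimum number of non-missing category scores needed
#'   to score the total; the default 8 is complete-case. The conventional
#'   relaxed rule scores when at least 6 of 8 categories are present,
#'   averaging over the present ones.
#' @return `score_haq_categories()`: vector of 8 category scores (or matrix).
#'   `score_haq_total()`: HAQ-DI total(s), multiples of 0.125 in [0, 3].
#' @examples
#' items <- rep(0L, 20); items[3] <- 2L          # some difficulty rising
#' flags <- rep(FALSE, 8)
#' cs <- score_haq_categories(items, flags, method = "SDI")
#' score_haq_total(cs)                           # 0.25
#' @export
score_haq_categories <- function(items, aid_flags, method = c("SDI", "ADI"),
                                 categories = haq_categories()) {
  method <- match.arg(method)
  if (is.matrix(items) || is.data.frame(items)) {
    items <- as.matrix(items)
    aid_flags <- as.matrix(aid_flags)
    out <- t(vapply(seq_len(nrow(items)), function(i) {
      score_haq_categories(items[i, ], aid_flags[i, ], method, categories)
    }, numeric(length(categories))))
    colnames(out) <- names(categories)
    return(out)
  }
  n_items <- length(unlist(categories))
  if (length(items) != n_items)
    stop("expected ", n_items, " HAQ items, got ", length(items))
  if (length(aid_flags) != length(categories))
    stop("expected ", length(categories), " aid flags, got ", length(aid_flags))
  bad <- which(!is.na(items) & !items %in% 0:3)
  if (length(bad))
    stop("HAQ item(s) ", paste(bad, collapse = ", "),
         " outside the response range {0, 1, 2, 3}")
  out <- vapply(seq_along(categories), function(ci) {
    vals <- items[categories[[ci]]]
    if (all(is.na(vals))) {
      return(NA_real_)
    }
    sc <- max(vals, na.rm = TRUE)
    if (method == "SDI" && isTRUE(aid_flags[ci]) && sc < 2) sc <- 2
    sc
  }, numeric(1))
  names(out) <- names(categories)
  out
}

#' @rdname score_haq_categories
#' @export
score_haq_total <- function(category_scores, min_categories = 8L) {
  if (is.matrix(category_scores) || is.data.frame(category_scores)) {
    return(apply(as.matrix(category_scores), 1L, score_haq_total,
                 min_categories = min_categories))
  }
  if (length(category_scores) != 8L)
    stop("expected 8 HAQ category scores, got ", length(category_scores))
  bad <- which(!is.na(category_scores) & !category_scores %in% 0:3)
  if (length(bad))
    stop("category score(s) ", paste(bad, collapse = ", "), " outside {0..3}")
  nm <- names(category_scores)
  if (is.null(nm)) nm <- names(haq_categories())
  n_ok <- sum(!is.na(category_scores))
  if (n_ok < min_categories) {
    if (n_ok < 8L && min_categories >= 8L)
      stop("missing HAQ category score(s): ",
           paste(nm[is.na(category_scores)], collapse = ", "))
    return(NA_real_)
  }
  mean(category_scores, na.rm = TRUE)
}

#' Score both instruments end to end
#'
#' Convenience wrapper: PF-10 raw and norm-based scores plus HAQ-DI totals
#' under both scoring methods for a whole sample.
#'
#' @param pf10 matrix (n x 10) of PF-10 responses in 1-3.
#' @param haq_items matrix (n x 20) of HAQ item responses in 0-3.
#' @param aid_flags logical matrix (n x 8) of aids/devices indicators.
#' @return data.frame with columns `pf10_raw`, `pf10_norm`, `haq_sdi`,
#'   `haq_adi`.
#' @export
score_sample <- function(pf10, haq_items, aid_flags) {
  raw <- score_pf10_raw(pf10)
  sdi <- score_haq_total(score_haq_categories(haq_items, aid_flags, "SDI"))
  adi <- score_haq_total(score_haq_categories(haq_items, aid_flags, "ADI"))
  data.frame(
    pf10_raw = raw,
    pf10_norm = pf10_norm_based(raw),
    haq_sdi = sdi,
    haq_adi = adi
  )
}

#' Attainable total scores of a scale
#'
#' The exhaustive, ordered set of total scores an instrument can produce:
#' 21 values (0, 5, ..., 100) for the PF-10 raw score and 25 values
#' (0, 0.125, ..., 3) for either HAQ-DI scoring method.
#'
#' @param scale_id one of `"PF10_RAW"`, `"PF10_NORM"`, `"HAQ_SDI"`,
#'   `"HAQ_ADI"`.
#' @param worst_first if `TRUE`, order from worst function to best; default
#'   orders from best function to worst (PF-10 descending, HAQ ascending is
#'   best-to-worst reversed — note the two scales run in opposite directions).
#' @return numeric vector of attainable values. For `PF10_NORM` these are the
#'   norm-based companions of the 21 raw values.
#' @examples
#' length(attainable_scores("PF10_RAW"))  # 21
#' length(attainable_scores("HAQ_SDI"))   # 25
#' @export
attainable_scores <- function(scale_id, worst_first = FALSE) {
  vals <- switch(scale_id,
    PF10_RAW  = seq(0, 100, by = 5),
    PF10_NORM = pf10_norm_based(seq(0, 100, by = 5)),
    HAQ_SDI   = ,
    HAQ_ADI   = seq(0, 3, by = 0.125),
    stop("unknown scale id: ", scale_id)
  )
  higher_is_better <- scale_id %in% c("PF10_RAW", "PF10_NORM")
  # best function first by default
  if (worst_first == higher_is_better) vals else rev(vals)
}
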