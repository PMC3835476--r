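#' Joint calibration of the PF-10 items and HAQ-DI category scores
#'
#' Calibrates the 10 reverse-coded PF-10 items (categories 0-2, 0 = no
#' limitation) and the 8 HAQ-DI category scores (0-3) together in one model.
#' Under `"MIRT2"` the PF-10 items load on dimension 1 and the HAQ categories
#' on dimension 2, with the latent correlation estimated.
#'
#' @param pf10_reversed integer matrix (n x 10) of reverse-coded PF-10
#'   responses in 0-2 (see [reverse_pf10_items()]).
#' @param haq_cats integer matrix (n x 8) of HAQ category scores in 0-3 (see
#'   [score_haq_categories()]); the same persons, in the same row order, as
#'   `pf10_reversed`.
#' @param model `"PCM"`, `"GPCM"` or `"MIRT2"`.
#' @param grid quadrature grid.
#' @param control EM control list, see [fit_calibration()].
#' @return a `calibration` object over the 18 joint items.
#' @export
co_calibrate <- function(pf10_reversed, haq_cats, model = "PCM",
                         grid = quad_grid(), control = list()) {
  pf <- as.matrix(pf10_reversed); hq <- as.matrix(haq_cats)
  if (nrow(pf) != nrow(hq))
    stop("person-set mismatch: ", nrow(pf), " PF-10 rows vs ",
         nrow(hq), " HAQ rows")
  if (ncol(pf) != 10L) stop("expected 10 reversed PF-10 items, got ", ncol(pf))
  if (ncol(hq) != 8L) stop("expected 8 HAQ category scores, got ", ncol(hq))
  if (any(!is.na(pf) & !pf %in% 0:2))
    stop("reversed PF-10 responses must be in {0, 1, 2}")
  if (any(!is.na(hq) & !hq %in% 0:3))
    stop("HAQ category scores must be in {0, 1, 2, 3}")
  if (is.null(colnames(pf))) colnames(pf) <- pf10_items()
  if (is.null(colnames(hq))) colnames(hq) <- names(haq_categories())
  x <- cbind(pf, hq)
  fit_calibration(x, model, dims = c(rep(1L, 10L), rep(2L, 8L)),
                  n_cat = c(rep(3L, 10L), rep(4L, 8L)),
                  grid = grid, control = control)
}

#' Instrument-specific sum-score EAP tables from a joint calibration
#'
#' Scoring runs with the item parameters held fixed at the jointly calibrated
#' values: one sum-score EAP table per instrument (21 attainable PF-10 sums,
#' 25 attainable HAQ category-score sums). For the between-item
#' two-dimensional model each instrument's table is computed on its own
#' dimension; integrating the other dimension out of the bivariate prior
#' leaves the standard-normal margin, so the two tables sit on concurrently
#' estimated, directly comparable EAP scales.
#'
#' @param joint a `calibration` object from [co_calibrate()].
#' @param grid quadrature grid.
#' @return list with `pf10` and `haq` score tables (class `score_table`).
#' @export
instrument_score_tables <- function(joint, grid = quad_grid()) {
  params <- joint$params
  if (length(unique(params$dim)) == 1L) {
    pf <- params[seq_len(10L), , drop = FALSE]
    hq <- params[-seq_len(10L), , drop = FALSE]
  } else {
    pf <- params[params$dim == 1L, , drop = FALSE]
    hq <- params[params$dim == 2L, , drop = FALSE]
  }
  pf$dim <- 1L; hq$dim <- 1L
  class(pf) <- class(hq) <- c("item_params", "data.frame")
  list(pf10 = sum_score_eap_table(pf, grid, instrument = "PF-10"),
       haq = sum_score_eap_table(hq, grid, instrument = "HAQ-DI"))
}

#' Nearest-EAP linking of two sum-score tables
#'
#' Links each attainable summed score on instrument A to the summed score on
#' instrument B whose EAP is closest on the latent scale. Ties are broken
#' toward the score indicating better function (the lower disability-coded
#' sum). Scores of A whose EAP lies beyond B's most extreme EAP are linked to
#' B's extreme score (boundary clipping, never extrapolation).
#'
#' @param table_a,table_b `score_table` objects on a common latent scale.
#' @return data.frame with columns `score_a`, `eap_a`, `score_b`, `eap_b`,
#'   one row per attainable score of A; `score_b` is monotone non-decreasing
#'   in `score_a`.
#' @export
nearest_link <- function(table_a, table_b) {
  if (!nrow(table_a) || !nrow(table_b)) stop("empty score table")
  idx <- vapply(table_a$eap, function(e) {
    d <- abs(e - table_b$eap)
    cand <- which(d == min(d))
    cand[1]  # ties toward better function: tables are sorted best-first
  }, integer(1))
  data.frame(score_a = table_a$sum_score, eap_a = table_a$eap,
             score_b = table_b$sum_score[idx], eap_b = table_b$eap[idx])
}

# observed-score conversions between disability-coded sums and scale metrics
pf10_sum_to_raw <- function(s) 100 - 5 * s
pf10_raw_to_sum <- function(raw) as.integer(round((100 - raw) / 5))
haq_sum_to_score <- function(s) s / 8
haq_score_to_sum <- function(v) as.integer(round(v * 8))

#' Build a PF-10 / HAQ-DI crosswalk
#'
#' The full linking procedure: score the HAQ categories under the requested
#' method, reverse-code the PF-10, co-calibrate the 18 joint items under the
#' requested model, compute instrument-specific sum-score EAP tables with the
#' joint parameters held fixed, and link every attainable total score on each
#' instrument to the nearest-EAP total score on the other. Norm-based PF-10
#' companions accompany every PF-10 raw score.
#'
#' @param pf10 matrix (n x 10) of PF-10 responses in original 1-3 coding.
#' @param haq_items matrix (n x 20) of HAQ item responses in 0-3.
#' @param aid_flags logical matrix (n x 8) of aids/devices indicators.
#' @param model `"PCM"`, `"GPCM"` or `"MIRT2"`.
#' @param method HAQ scoring method, `"SDI"` or `"ADI"`.
#' @param grid quadrature grid.
#' @param control EM control list.
#' @return object of class `linking_result`: list with the `calibration`,
#'   the two score `tables`, and the `crosswalk` (class `crosswalk`).
#' @export
build_crosswalk <- function(pf10, haq_items, aid_flags,
                            model = "PCM", method = c("SDI", "ADI"),
                            grid = quad_grid(), control = list()) {
  method <- match.arg(method)
  rev_pf <- reverse_pf10_items(pf10)
  cats <- score_haq_categories(haq_items, aid_flags, method)
  joint <- co_calibrate(rev_pf, cats, model, grid, control)
  tabs <- instrument_score_tables(joint, grid)
  link_h2p <- nearest_link(tabs$haq, tabs$pf10)
  link_p2h <- nearest_link(tabs$pf10, tabs$haq)
  h2p <- data.frame(
    haq = haq_sum_to_score(link_h2p$score_a),
    pf10 = pf10_sum_to_raw(link_h2p$score_b),
    eap_haq = link_h2p$eap_a, eap_pf10 = link_h2p$eap_b)
  h2p$pf10_norm <- pf10_norm_based(h2p$pf10)
  p2h <- data.frame(
    pf10 = pf10_sum_to_raw(link_p2h$score_a),
    haq = haq_sum_to_score(link_p2h$score_b),
    eap_pf10 = link_p2h$eap_a, eap_haq = link_p2h$eap_b)
  p2h$pf10_norm <- pf10_norm_based(p2h$pf10)
  cw <- new_crosswalk(
    haq_to_pf10 = h2p[order(h2p$haq),
                      c("haq", "pf10", "pf10_norm", "eap_haq", "eap_pf10")],
    pf10_to_haq = p2h[order(-p2h$pf10),
                      c("pf10", "pf10_norm", "haq", "eap_pf10", "eap_haq")],
    method = method, model = model,
    meta = list(n = joint$n,
                rho = if (!is.na(joint$rho)) joint$rho else NULL))
  structure(list(calibration = joint, tables = tabs, crosswalk = cw),
            class = "linking_result")
}

#' @export
print.linking_result <- function(x, ...) {
  print(x$calibration)
  print(x$crosswalk)
  invisible(x)
}

#' Compare crosswalks built under the nested IRT models
#'
#' Builds crosswalks under each requested model and HAQ scoring method,
#' applies them within-sample, and reports (i) the ICC(A,1) agreement between
#' observed and predicted total scores for each direction (HAQ from PF-10 and
#' PF-10 from HAQ, per scoring method) and (ii) pairwise Pearson correlations
#' between the predictions of the different models.
#'
#' @inheritParams build_crosswalk
#' @param models character vector of models to compare.
#' @param methods HAQ scoring methods to include.
#' @return object of class `model_comparison`: list with `icc` (data.frame:
#'   direction x model ICC with 95% CI), `prediction_cor` (data.frame of
#'   pairwise model correlations per direction), and `crosswalks`.
#' @export
compare_models <- function(pf10, haq_items, aid_flags,
                           models = c("PCM", "GPCM", "MIRT2"),
                           methods = c("SDI", "ADI"),
                           grid = quad_grid(), control = list()) {
  obs <- score_sample(pf10, haq_items, aid_flags)
  cws <- list()
  for (method in methods) {
    for (model in models) {
      cws[[paste(method, model, sep = ".")]] <-
        build_crosswalk(pf10, haq_items, aid_flags, model, method,
                        grid, control)$crosswalk
    }
  }
  directions <- unlist(lapply(methods, function(m)
    c(paste0("HAQ-", m, " from PF-10"), paste0("PF-10 from HAQ-", m))),
    use.names = FALSE)
  pred <- list()
  icc_rows <- list()
  for (method in methods) {
    obs_haq <- if (method == "SDI") obs$haq_sdi else obs$haq_adi
    for (model in models) {
      cw <- cws[[paste(method, model, sep = ".")]]
      p_haq <- apply_crosswalk(cw, obs$pf10_raw, from = "pf10")$haq
      p_pf <- apply_crosswalk(cw, obs_haq, from = "haq")$pf10
      pred[[paste("HAQ-", method, " from PF-10", sep = "")]][[model]] <- p_haq
      pred[[paste("PF-10 from HAQ-", method, sep = "")]][[model]] <- p_pf
      i1 <- icc_a1(obs_haq, p_haq)
      i2 <- icc_a1(obs$pf10_raw, p_pf)
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        direction = paste0("HAQ-", method, " from PF-10"), model = model,
        icc = i1$icc, lower = i1$ci[1], upper = i1$ci[2])
      icc_rows[[length(icc_rows) + 1L]] <- data.frame(
        direction = paste0("PF-10 from HAQ-", method), model = model,
        icc = i2$icc, lower = i2$ci[1], upper = i2$ci[2])
    }
  }
  cor_rows <- list()
  for (dir in names(pred)) {
    ms <- names(pred[[dir]])
    for (i in seq_along(ms)) for (k in seq_along(ms)) if (i < k) {
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        direction = dir, model_1 = ms[i], model_2 = ms[k],
        r = stats::cor(pred[[dir]][[ms[i]]], pred[[dir]][[ms[k]]]))
    }
  }
  out <- list(icc = do.call(rbind, icc_rows),
              prediction_cor = do.call(rbind, cor_rows),
              predictions = pred, crosswalks = cws)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Agreement (ICC(A,1), 95% CI) between observed and predicted scores:\n")
  df <- x$icc
  df$`ICC (95% CI)` <- sprintf("%.3f (%.3f to %.3f)", df$icc, df$lower, df$upper)
  print.data.frame(df[, c("direction", "model", "ICC (95% CI)")],
                   row.names = FALSE)
  cat("\nPairwise correlations between model predictions:\n")
  print.data.frame(x$prediction_cor, row.names = FALSE, digits = 4)
  invisible(x)
}
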