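#' Item-fit diagnostics for polytomous IRT calibrations
#'
#' Assesses item fit by comparing observed and model-expected mean item scores
#' within groups of low-, average- and high-scoring persons. Persons are
#' grouped into EAP tertiles via value-based (type-1) quantile cutpoints, so
#' persons with identical EAPs always share a group and the grouping is
#' invariant to relabeling and to sample duplication. For each
#' group the model-expected mean is the average, over group members, of the
#' expected item score integrated over each member's posterior latent
#' distribution. The per-group effect size is
#' `ES = |observed - expected| / m_j`, where `m_j` is the item's number of
#' response categories, so an ES of 0.10 corresponds to an observed-vs-
#' expected score-frequency difference of 2.5% for 4-category items and 3.33%
#' for 3-category items (see [es_to_frequency()]). Fit is acceptable when
#' every ES is below the cutoff (default 0.10).
#'
#' A chi-square-type statistic accompanies the effect sizes: the quadratic
#' form of the grouped score residuals with a plug-in covariance taken from
#' the model-implied score variance of each group member (an approximation to
#' the Lagrange-multiplier tests used for polytomous items; the ES criterion
#' is the primary gate).
#'
#' @param responses integer response matrix (persons x items, categories
#'   `0 .. n_cat - 1`).
#' @param params fitted [item_params()] for the same items (unidimensional).
#' @param n_groups number of latent-score groups (default 3: low/average/high).
#' @param cutoff acceptance cutoff on every per-group ES (default 0.10).
#' @param grid quadrature grid.
#' @return object of class `fit_report`: data.frame with one row per item
#'   (`item`, `n_cat`, per-group `n`, observed and expected means and `es`,
#'   `lm_stat`, `df`, `p`), with attributes `cutoff` and `pass`
#'   (`TRUE` iff all ES < cutoff).
#' @export
item_fit <- function(responses, params, n_groups = 3L, cutoff = 0.10,
                     grid = quad_grid()) {
  x <- as.matrix(responses)
  if (ncol(x) != nrow(params))
    stop("responses have ", ncol(x), " items but params describe ", nrow(params))
  if (length(unique(params$dim)) > 1L) {
    # between-item multidimensional calibration: assess each dimension's item
    # block against its own (standard normal) margin
    parts <- lapply(sort(unique(params$dim)), function(d) {
      sel <- params$dim == d
      p <- params[sel, , drop = FALSE]
      p$dim <- 1L
      class(p) <- c("item_params", "data.frame")
      item_fit(x[, sel, drop = FALSE], p, n_groups, cutoff, grid)
    })
    out <- do.call(rbind, lapply(parts, as.data.frame))
    es_cols <- grep("^es_", names(out))
    attr(out, "cutoff") <- cutoff
    attr(out, "pass") <- all(as.matrix(out[, es_cols]) < cutoff)
    attr(out, "groups") <- attr(parts[[1]], "groups")
    class(out) <- c("fit_report", "data.frame")
    return(out)
  }
  em <- eap_matrix(x, params, grid)
  n <- nrow(x)
  # tertile (or n_groups-tile) boundaries on the EAP distribution; value-based
  # type-1 quantile cutpoints keep tied EAPs in one group, so the grouping is
  # invariant to person relabeling and to sample duplication
  cuts <- stats::quantile(em$eap, seq_len(n_groups - 1L) / n_groups, type = 1)
  grp <- as.integer(cut(em$eap, breaks = c(-Inf, cuts, Inf), labels = FALSE))
  # merge empty groups (possible only for tiny n) with their neighbour
  tab <- tabulate(grp, n_groups)
  while (any(tab == 0L)) {
    g0 <- which(tab == 0L)[1]
    nb <- if (g0 > 1L) g0 - 1L else g0 + 1L
    message("item_fit: empty group ", g0, " merged with group ", nb)
    grp[grp == g0] <- nb
    grp <- match(grp, sort(unique(grp)))
    n_groups <- max(grp)
    tab <- tabulate(grp, n_groups)
  }
  group_labels <- if (n_groups == 3L) c("low", "average", "high")
                  else paste0("g", seq_len(n_groups))

  nodes <- grid$nodes
  rows <- lapply(seq_len(nrow(params)), function(j) {
    mom <- item_score_moments(
      category_probabilities(nodes, thresholds(params, j), params$a[j]))
    e_i <- as.vector(em$post %*% mom$mean)        # posterior-expected score
    # model-implied variance of the observed score per person
    v_i <- as.vector(em$post %*% mom$var) +
      pmax(as.vector(em$post %*% mom$mean^2) - e_i^2, 0)
    ok <- !is.na(x[, j])
    rec <- list(item = params$item[j], n_cat = params$n_cat[j])
    lm_num <- lm_den <- numeric(n_groups)
    for (g in seq_len(n_groups)) {
      sel <- ok & grp == g
      obs <- mean(x[sel, j])
      expd <- mean(e_i[sel])
      rec[[paste0("n_", group_labels[g])]] <- sum(sel)
      rec[[paste0("obs_", group_labels[g])]] <- obs
      rec[[paste0("exp_", group_labels[g])]] <- expd
      rec[[paste0("es_", group_labels[g])]] <-
        abs(obs - expd) / params$n_cat[j]
      lm_num[g] <- sum(x[sel, j] - e_i[sel])
      lm_den[g] <- sum(v_i[sel])
    }
    rec$lm_stat <- sum(lm_num^2 / pmax(lm_den, 1e-12))
    rec$df <- n_groups - 1L
    rec$p <- stats::pchisq(rec$lm_stat, rec$df, lower.tail = FALSE)
    as.data.frame(rec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  es_cols <- grep("^es_", names(out))
  attr(out, "cutoff") <- cutoff
  attr(out, "pass") <- all(as.matrix(out[, es_cols]) < cutoff)
  attr(out, "groups") <- group_labels
  class(out) <- c("fit_report", "data.frame")
  out
}

#' @export
print.fit_report <- function(x, ...) {
  es_cols <- grep("^es_", names(x))
  cat("Item fit report: ", nrow(x), " items, max ES = ",
      sprintf("%.4f", max(as.matrix(x[, es_cols]))),
      ", cutoff ", attr(x, "cutoff"),
      if (attr(x, "pass")) " -- acceptable fit (all ES < cutoff)"
      else " -- MISFIT (ES at or above cutoff)", "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Convert an item-fit ES cutoff to a score-frequency difference
#'
#' The ES statistic divides the absolute observed-minus-expected mean item
#' score by the item's number of response categories, so a cutoff translates
#' to a percentage difference between observed and expected score
#' frequencies: `cutoff / m * 100`. An ES cutoff of 0.10 corresponds to 2.5%
#' for 4-category (HAQ-DI) items and 3.33% for 3-category (PF-10) items.
#'
#' @param cutoff ES cutoff (>= 0).
#' @param m number of response categories (>= 2).
#' @param digits rounding for the returned percentage (default 2).
#' @return frequency difference in percent.
#' @examples
#' es_to_frequency(0.10, 4)  # 2.5
#' es_to_frequency(0.10, 3)  # 3.33
#' @export
es_to_frequency <- function(cutoff, m, digits = 2) {
  stopifnot(cutoff >= 0, m >= 2)
  round(cutoff / m * 100, digits)
}

#' Write an item-fit report alongside item parameters
#'
#' Serialises fitted parameters and per-item fit statistics to one structured
#' text table (item, discrimination, thresholds, dimension, per-group ES, fit
#' statistic, df, p), the layout used for published item-parameter
#' supplements.
#'
#' @param params fitted [item_params()].
#' @param fit a `fit_report` from [item_fit()] for the same items.
#' @param path output file.
#' @param meta named list of metadata comment lines.
#' @return the path, invisibly.
#' @export
write_fit_report <- function(params, fit, path, meta = list()) {
  stopifnot(identical(params$item, fit$item))
  keep <- c(grep("^es_", names(fit), value = TRUE), "lm_stat", "df", "p")
  merged <- cbind(as.data.frame(params), fit[, keep])
  meta$cutoff <- attr(fit, "cutoff")
  meta$pass <- attr(fit, "pass")
  write_item_params(merged, path, meta)
}
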