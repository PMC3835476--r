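#' EAP estimation of latent disability from a response pattern
#'
#' Posterior mean and SD of the latent score(s) given an observed response
#' pattern, computed on the quadrature grid under the standard-normal prior
#' (bivariate at correlation `rho` for two-dimensional parameter sets).
#' Missing responses are skipped; an all-missing pattern is an error.
#'
#' @param pattern integer vector, one response per item (`0 .. n_cat - 1`,
#'   `NA` = missing).
#' @param params an [item_params()] object.
#' @param grid quadrature grid from [quad_grid()].
#' @param rho latent correlation (two-dimensional parameter sets only).
#' @return data.frame with one row per dimension: `dim`, `eap`, `psd`.
#' @export
eap_pattern <- function(pattern, params, grid = quad_grid(), rho = NULL) {
  if (length(pattern) != nrow(params))
    stop("pattern length ", length(pattern), " != ", nrow(params), " items")
  if (all(is.na(pattern))) stop("all-missing response pattern")
  nodes <- grid$nodes
  two_dim <- length(unique(params$dim)) > 1L
  lik_dim <- function(d) {
    ll <- numeric(length(nodes))
    for (j in which(params$dim == d)) {
      if (is.na(pattern[j])) next
      p <- category_probabilities(nodes, thresholds(params, j), params$a[j])
      ll <- ll + log(pmax(p[, pattern[j] + 1L], 1e-300))
    }
    exp(ll - max(ll))
  }
  if (!two_dim) {
    f <- lik_dim(params$dim[1]) * grid$weights
    f <- f / sum(f)
    m <- sum(nodes * f)
    v <- sum(nodes^2 * f) - m^2
    return(data.frame(dim = params$dim[1], eap = m, psd = sqrt(max(v, 0))))
  }
  if (is.null(rho)) stop("two-dimensional parameters need `rho`")
  W <- quad_weights_2d(nodes, rho)
  f <- (lik_dim(1L) * W) * rep(lik_dim(2L), each = length(nodes))
  f <- f / sum(f)
  m1 <- sum(rowSums(f) * nodes); m2 <- sum(colSums(f) * nodes)
  v1 <- sum(rowSums(f) * nodes^2) - m1^2
  v2 <- sum(colSums(f) * nodes^2) - m2^2
  data.frame(dim = 1:2, eap = c(m1, m2),
             psd = sqrt(pmax(c(v1, v2), 0)))
}

# posterior n x Q matrix and EAPs for a whole response matrix (1-D params)
eap_matrix <- function(responses, params, grid = quad_grid()) {
  x <- as.matrix(responses)
  nodes <- grid$nodes
  n <- nrow(x); Q <- length(nodes)
  LL <- matrix(log(grid$weights), n, Q, byrow = TRUE)
  for (j in seq_len(nrow(params))) {
    lp <- t(log(pmax(category_probabilities(nodes, thresholds(params, j),
                                            params$a[j]), 1e-300)))
    ok <- which(!is.na(x[, j]))
    LL[ok, ] <- LL[ok, ] + lp[x[ok, j] + 1L, , drop = FALSE]
  }
  mx <- LL[cbind(seq_len(n), max.col(LL, ties.method = "first"))]
  post <- exp(LL - mx)
  post <- post / rowSums(post)
  eap <- as.vector(post %*% nodes)
  psd <- sqrt(pmax(as.vector(post %*% nodes^2) - eap^2, 0))
  list(post = post, eap = eap, psd = psd)
}

#' Sum-score distribution over the quadrature grid
#'
#' Lord-Wingersky recursion: the conditional distribution of the summed item
#' score `S` given each quadrature node, built up item by item by convolving
#' category probabilities. At every node the probabilities over the attainable
#' sums add to 1.
#'
#' @param params a unidimensional [item_params()] object.
#' @param grid quadrature grid from [quad_grid()].
#' @return matrix with `length(grid$nodes)` rows and `S_max + 1` columns
#'   (`S_max = sum(n_cat - 1)`); entry (q, s+1) is `P(S = s | theta_q)`.
#' @export
sum_score_posterior <- function(params, grid = quad_grid()) {
  if (length(unique(params$dim)) > 1L)
    stop("sum-score recursion requires a unidimensional item set")
  nodes <- grid$nodes
  f <- matrix(1, length(nodes), 1L)
  for (j in seq_len(nrow(params))) {
    P <- category_probabilities(nodes, thresholds(params, j), params$a[j])
    m <- ncol(P)
    g <- matrix(0, length(nodes), ncol(f) + m - 1L)
    for (k in seq_len(m)) {
      idx <- k:(k + ncol(f) - 1L)
      g[, idx] <- g[, idx] + f * P[, k]
    }
    f <- g
  }
  colnames(f) <- 0:(ncol(f) - 1L)
  f
}

#' Sum-score EAP table
#'
#' For every attainable summed score `s`, the EAP of the latent score given
#' `S = s`:
#' `theta(s) = sum_q theta_q P(s | theta_q) w_q / sum_q P(s | theta_q) w_q`,
#' with its posterior SD. Under the disability-direction coding used here
#' (items scored 0 = best function), `theta(s)` is strictly increasing in `s`.
#'
#' @inheritParams sum_score_posterior
#' @param instrument optional instrument label stored with the table.
#' @return data.frame of class `score_table` with columns `sum_score`, `eap`,
#'   `psd`.
#' @export
sum_score_eap_table <- function(params, grid = quad_grid(), instrument = NULL) {
  F <- sum_score_posterior(params, grid)
  w <- grid$weights; nodes <- grid$nodes
  marg <- as.vector(crossprod(F, w))
  if (any(marg <= 1e-300))
    stop("attainable sum score(s) with zero marginal probability: ",
         paste(which(marg <= 1e-300) - 1L, collapse = ", "))
  eap <- as.vector(crossprod(F, w * nodes)) / marg
  e2 <- as.vector(crossprod(F, w * nodes^2)) / marg
  out <- data.frame(sum_score = 0:(ncol(F) - 1L),
                    eap = eap, psd = sqrt(pmax(e2 - eap^2, 0)))
  if (any(diff(out$eap) <= 0))
    stop("sum-score EAPs are not strictly increasing; check the item set")
  attr(out, "instrument") <- instrument
  class(out) <- c("score_table", "data.frame")
  out
}

#' @export
print.score_table <- function(x, ...) {
  inst <- attr(x, "instrument")
  cat("Sum-score EAP table", if (!is.null(inst)) paste0(" (", inst, ")"),
      ": ", nrow(x), " attainable scores, EAP range [",
      sprintf("%.3f", min(x$eap)), ", ", sprintf("%.3f", max(x$eap)),
      "] (higher = worse function)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
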