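#' Quadrature grids for the latent prior
#'
#' Fixed rectangular quadrature: `n_nodes` equally spaced nodes on `bounds`
#' with standard-normal density weights renormalised to sum to 1. For
#' two-dimensional (between-item) models, [quad_weights_2d()] returns the
#' matrix of bivariate standard-normal weights at latent correlation `rho`
#' over the product grid, again renormalised.
#'
#' @param n_nodes number of nodes (default 61).
#' @param bounds latent-scale interval covered by the grid.
#' @return `quad_grid()`: list with `nodes` and `weights`.
#'   `quad_weights_2d()`: an `n x n` weight matrix over the product grid.
#' @export
quad_grid <- function(n_nodes = 61L, bounds = c(-6, 6)) {
  nodes <- seq(bounds[1], bounds[2], length.out = n_nodes)
  w <- stats::dnorm(nodes)
  list(nodes = nodes, weights = w / sum(w))
}

#' @rdname quad_grid
#' @param nodes node positions of the one-dimensional grid.
#' @param rho latent correlation, in (-1, 1).
#' @export
quad_weights_2d <- function(nodes, rho) {
  if (!is.finite(rho) || abs(rho) >= 1) stop("`rho` must be in (-1, 1)")
  q2 <- outer(nodes^2, nodes^2, "+")
  cross <- outer(nodes, nodes)
  logw <- -(q2 - 2 * rho * cross) / (2 * (1 - rho^2))
  w <- exp(logw - max(logw))
  w / sum(w)
}

#' Category response probabilities of the (generalized) partial credit model
#'
#' Adjacent-category logit model: for an item with categories
#' `k = 0, ..., m - 1`, discrimination `a` and thresholds `b_1, ..., b_{m-1}`,
#' `P(X = k | theta)` is proportional to
#' `exp(sum_{h <= k} a (theta - b_h))`. The PCM is the special case `a = 1`.
#'
#' @param theta numeric vector of latent scores (finite).
#' @param b numeric vector of `m - 1` thresholds.
#' @param a discrimination (> 0).
#' @return matrix, `length(theta)` rows by `m` columns, rows summing to 1.
#' @examples
#' category_probabilities(0, b = c(-1, 1))   # 0.212 0.576 0.212
#' @export
category_probabilities <- function(theta, b, a = 1) {
  if (any(!is.finite(theta))) stop("`theta` must be finite")
  b <- b[!is.na(b)]
  m <- length(b) + 1L
  cb <- c(0, cumsum(b))
  logits <- a * (outer(theta, 0:(m - 1L)) -
                 matrix(cb, length(theta), m, byrow = TRUE))
  mx <- logits[cbind(seq_along(theta), max.col(logits, ties.method = "first"))]
  e <- exp(logits - mx)
  e / rowSums(e)
}

# list of Q x m_j probability (or log-probability) matrices, one per item
item_prob_mats <- function(params, nodes, log = FALSE) {
  bl <- thresholds(params)
  lapply(seq_len(nrow(params)), function(j) {
    p <- category_probabilities(nodes, bl[[j]], params$a[j])
    if (log) log(pmax(p, 1e-300)) else p
  })
}

# expected item score and conditional score variance at each node
item_score_moments <- function(pmat) {
  k <- 0:(ncol(pmat) - 1L)
  mu <- as.vector(pmat %*% k)
  v <- as.vector(pmat %*% (k^2)) - mu^2
  list(mean = mu, var = pmax(v, 0))
}

#' Test and item information functions
#'
#' Adjacent-category model information: the item information at `theta` is
#' `a_j^2 * Var(X_j | theta)` and the test information is the sum over items.
#' Under the convention used throughout this package, higher `theta` means
#' worse physical function, so an instrument informative at high `theta`
#' measures severe disability precisely.
#'
#' @param params an [item_params()] object (unidimensional).
#' @param theta numeric vector of latent scores at which to evaluate.
#' @return data.frame with `theta`, per-item information columns, and `total`.
#' @export
test_information <- function(params, theta = seq(-4, 4, by = 0.1)) {
  pm <- item_prob_mats(params, theta)
  info <- vapply(seq_len(nrow(params)), function(j) {
    params$a[j]^2 * item_score_moments(pm[[j]])$var
  }, numeric(length(theta)))
  info <- matrix(info, nrow = length(theta))
  colnames(info) <- params$item
  out <- data.frame(theta = theta)
  out <- cbind(out, info)
  out$total <- rowSums(info)
  out
}
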