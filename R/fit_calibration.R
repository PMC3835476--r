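#' Marginal maximum likelihood calibration of polytomous IRT models
#'
#' Fits the partial credit model (PCM), the generalized partial credit model
#' (GPCM), or a between-item two-dimensional GPCM (MIRT2) to an integer
#' response matrix by marginal maximum likelihood, using an EM algorithm over
#' a fixed rectangular quadrature grid. Identification fixes the latent prior
#' to standard normal on each dimension; the PCM additionally fixes all
#' discriminations at 1. For MIRT2 each item loads on exactly one dimension
#' and the correlation `rho` between the two standard-normal dimensions is
#' estimated: during EM by the closed-form update on posterior cross-moments,
#' and, once the item parameters have converged, by a profile-likelihood grid
#' search over (-0.95, 0.95) in steps of 0.01, refined once to 0.001.
#'
#' @param responses integer matrix, persons in rows, items in columns; item
#'   `j` takes values `0 .. n_cat[j] - 1`; `NA` denotes a missing response.
#'   Column names, when present, become item identifiers.
#' @param model `"PCM"`, `"GPCM"` or `"MIRT2"`.
#' @param dims integer vector (length = number of items) of dimension
#'   assignments in \{1, 2\}; required for `"MIRT2"`, ignored otherwise.
#' @param n_cat per-item category counts; default is the observed maximum + 1.
#' @param grid quadrature grid from [quad_grid()] (used per dimension).
#' @param unobserved what to do when an item category in `0 .. n_cat - 1` has
#'   no observations: `"collapse"` merges it into its nearest observed
#'   neighbour (with a warning), `"error"` aborts.
#' @param control list: `tol` (convergence tolerance on the maximum absolute
#'   parameter change, default 1e-4), `max_iter` (default 2000), `mstep_maxit`
#'   (BFGS iterations per item per M-step, default 10), `rho_start`
#'   (default 0.5), `verbose`.
#' @return object of class `calibration`: a list with `model`, `params`
#'   (an [item_params()] data.frame), `rho` (MIRT2 only), `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `n`, `grid`, and `collapsed`
#'   (category-collapse bookkeeping). Sample sizes below a few hundred
#'   persons give unstable threshold estimates for 4-category items; a
#'   warning is issued below n = 100.
#' @examples
#' \donttest{
#' par <- default_item_params("PCM")
#' th <- simulate_thetas(400, seed = 1)
#' x <- simulate_item_responses(th, par, seed = 2)
#' fit <- fit_calibration(x, "PCM")
#' fit$loglik
#' }
#' @export
fit_calibration <- function(responses, model = c("PCM", "GPCM", "MIRT2"),
                            dims = NULL, n_cat = NULL, grid = quad_grid(),
                            unobserved = c("collapse", "error"),
                            control = list()) {
  model <- match.arg(model)
  unobserved <- match.arg(unobserved)
  ctl <- utils::modifyList(list(tol = 1e-4, max_iter = 2000L, mstep_maxit = 10L,
                                rho_start = 0.5, verbose = FALSE), control)
  x <- as.matrix(responses)
  storage.mode(x) <- "integer"
  n <- nrow(x); J <- ncol(x)
  if (n < 2L) stop("need at least 2 persons")
  if (n < 100L) warning("n = ", n, " persons: estimates will be unstable")
  items <- colnames(x)
  if (is.null(items)) items <- paste0("item", seq_len(J))
  if (model == "MIRT2") {
    if (is.null(dims) || length(dims) != J || !all(dims %in% 1:2))
      stop("MIRT2 requires `dims`: one value in {1, 2} per item")
    dims <- as.integer(dims)
    if (length(unique(dims)) != 2L)
      stop("MIRT2 requires items on both dimensions")
  } else {
    dims <- rep(1L, J)
  }
  if (is.null(n_cat)) n_cat <- apply(x, 2L, max, na.rm = TRUE) + 1L
  n_cat <- as.integer(rep_len(n_cat, J))

  # check category coverage; collapse or abort
  collapsed <- vector("list", J); names(collapsed) <- items
  for (j in seq_len(J)) {
    obs <- sort(unique(x[!is.na(x[, j]), j]))
    if (length(obs) < 2L)
      stop("item ", items[j], ": fewer than 2 observed categories")
    full <- 0:(n_cat[j] - 1L)
    if (!all(full %in% obs)) {
      if (unobserved == "error")
        stop("item ", items[j], ": unobserved categor(ies) ",
             paste(setdiff(full, obs), collapse = ", "))
      remap <- match(x[, j], obs) - 1L
      collapsed[[j]] <- list(observed = obs, n_cat_new = length(obs))
      warning("item ", items[j], ": collapsing to ", length(obs),
              " observed categories")
      x[, j] <- remap
      n_cat[j] <- length(obs)
    }
  }

  # classical adjacent-category starting thresholds: log(n_{k-1} / n_k)
  b <- lapply(seq_len(J), function(j) {
    cnt <- tabulate(x[, j] + 1L, nbins = n_cat[j]) + 0.5
    log(cnt[-n_cat[j]] / cnt[-1])
  })
  a <- rep(1, J)
  est_a <- model != "PCM"

  # 0/1 indicator matrices (missing -> zero row), built once
  ind <- lapply(seq_len(J), function(j) {
    m <- matrix(0, n, n_cat[j])
    ok <- which(!is.na(x[, j]))
    m[cbind(ok, x[ok, j] + 1L)] <- 1
    m
  })

  nodes <- grid$nodes; Q <- length(nodes)
  logw <- log(grid$weights)
  rho <- if (model == "MIRT2") ctl$rho_start else NA_real_

  dim_loglik <- function(d) {
    # n x Q log-likelihood of the responses on dimension d
    LL <- matrix(0, n, Q)
    for (j in which(dims == d)) {
      lp <- t(log(pmax(category_probabilities(nodes, b[[j]], a[j]), 1e-300)))
      ok <- which(!is.na(x[, j]))
      LL[ok, ] <- LL[ok, ] + lp[x[ok, j] + 1L, , drop = FALSE]
    }
    LL
  }

  par_vec <- function() c(unlist(b), if (est_a) log(a), if (model == "MIRT2") rho)

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (model == "MIRT2") {
      L1 <- exp(dim_loglik(1L)); L2 <- exp(dim_loglik(2L))
      W <- quad_weights_2d(nodes, rho)
      A1 <- L1 %*% W          # n x Q, integrates dim-1 likelihood forward
      A2 <- L2 %*% t(W)
      den <- rowSums(A1 * L2)
      ll <- sum(log(den))
      post <- list(`1` = L1 * A2 / den, `2` = L2 * A1 / den)
      # posterior cross-moments for the rho update
      S11 <- sum(((L1 * rep(nodes, each = n)) %*% W) *
                 (L2 * rep(nodes, each = n)) / den)
      S20 <- sum(post[["1"]] * rep(nodes^2, each = n))
      S02 <- sum(post[["2"]] * rep(nodes^2, each = n))
      rho_obj <- function(r) {
        -n * log(1 - r^2) / 2 - (S20 - 2 * r * S11 + S02) / (2 * (1 - r^2)) +
          (S20 + S02) / 2
      }
      rho_new <- stats::optimize(rho_obj, c(-0.949, 0.949), maximum = TRUE)$maximum
    } else {
      LL <- dim_loglik(1L) + matrix(logw, n, Q, byrow = TRUE)
      mx <- LL[cbind(seq_len(n), max.col(LL, ties.method = "first"))]
      p <- exp(LL - mx)
      den <- rowSums(p)
      ll <- sum(log(den) + mx)
      post <- list(`1` = p / den)
      rho_new <- rho
    }
    ll_trace <- c(ll_trace, ll)
    old <- par_vec()
    for (j in seq_len(J)) {
      R <- crossprod(post[[as.character(dims[j])]], ind[[j]])  # Q x m_j
      up <- mstep_item(R, nodes, b[[j]], a[j], est_a, ctl$mstep_maxit)
      b[[j]] <- up$b; a[j] <- up$a
    }
    rho <- rho_new
    delta <- max(abs(par_vec() - old))
    if (ctl$verbose)
      message(sprintf("iter %3d  loglik %.4f  max|change| %.2e", iter, ll, delta))
    if (delta < ctl$tol) { converged <- TRUE; break }
    if (iter >= ctl$max_iter) break
  }
  if (!converged) {
    stop(errorCondition(
      paste0("EM did not converge in ", ctl$max_iter,
             " iterations (last max parameter change ", format(delta),
             "); log-likelihood trace attached as condition field `em_trace`"),
      em_trace = ll_trace, class = c("pfhaq_nonconvergence", "error")))
  }

  if (model == "MIRT2") {
    # profile-likelihood estimate of rho with item parameters held fixed
    L1 <- exp(dim_loglik(1L)); L2 <- exp(dim_loglik(2L))
    prof <- function(r) sum(log(rowSums((L1 %*% quad_weights_2d(nodes, r)) * L2)))
    coarse <- seq(-0.94, 0.94, by = 0.01)
    ll_c <- vapply(coarse, prof, numeric(1))
    r0 <- coarse[which.max(ll_c)]
    fine <- seq(max(-0.949, r0 - 0.01), min(0.949, r0 + 0.01), by = 0.001)
    ll_f <- vapply(fine, prof, numeric(1))
    rho <- fine[which.max(ll_f)]
    ll <- max(ll_f)
  } else {
    # log-likelihood at the final parameter values
    LL <- dim_loglik(1L) + matrix(logw, n, Q, byrow = TRUE)
    mx <- LL[cbind(seq_len(n), max.col(LL, ties.method = "first"))]
    ll <- sum(log(rowSums(exp(LL - mx))) + mx)
  }

  params <- item_params(items, n_cat, b = b, a = a, dim = dims)
  out <- list(model = model, params = params, rho = rho, loglik = ll,
              loglik_trace = ll_trace, n_iter = iter, converged = converged,
              n = n, grid = grid,
              collapsed = Filter(Negate(is.null), collapsed))
  class(out) <- "calibration"
  out
}

# Expected complete-data log-likelihood maximisation for one item.
# R: Q x m expected counts; analytic gradient, BFGS (a partial M-step keeps
# EM monotone as long as the expected log-likelihood does not decrease).
mstep_item <- function(R, nodes, b0, a0, est_a, maxit = 10L) {
  m <- length(b0) + 1L
  Nq <- rowSums(R)
  O <- vapply(seq_len(m - 1L), function(h) {
    rowSums(R[, (h + 1L):m, drop = FALSE])
  }, numeric(nrow(R)))
  negll <- function(par) {
    bb <- par[seq_len(m - 1L)]
    aa <- if (est_a) exp(par[m]) else a0
    P <- category_probabilities(nodes, bb, aa)
    -sum(R * log(pmax(P, 1e-300)))
  }
  grad <- function(par) {
    bb <- par[seq_len(m - 1L)]
    aa <- if (est_a) exp(par[m]) else a0
    P <- category_probabilities(nodes, bb, aa)
    ES <- vapply(seq_len(m - 1L), function(h) {
      rowSums(P[, (h + 1L):m, drop = FALSE])
    }, numeric(length(nodes)))
    g_b <- aa * colSums(O - Nq * ES)
    if (!est_a) return(g_b)
    cb <- c(0, cumsum(bb))
    Tq <- outer(nodes, 0:(m - 1L)) - matrix(cb, length(nodes), m, byrow = TRUE)
    dll_da <- sum(R * Tq) - sum(Nq * rowSums(P * Tq))
    c(g_b, -aa * dll_da)
  }
  par0 <- c(b0, if (est_a) log(a0))
  f0 <- negll(par0)
  o <- stats::optim(par0, negll, grad, method = "BFGS",
                    control = list(maxit = maxit))
  if (!is.finite(o$value) || o$value > f0) {
    return(list(b = b0, a = a0))  # keep old values: never decrease
  }
  list(b = o$par[seq_len(m - 1L)], a = if (est_a) exp(o$par[m]) else a0)
}

#' @export
print.calibration <- function(x, ...) {
  cat("Calibration (", x$model, "): ", nrow(x$params), " items, n = ", x$n,
      "\n", sep = "")
  cat("log-likelihood ", format(x$loglik, digits = 10), ", ", x$n_iter,
      " EM iterations", if (!x$converged) " (NOT converged)", "\n", sep = "")
  if (!is.na(x$rho)) cat("latent correlation rho =", format(x$rho), "\n")
  if (length(x$collapsed))
    cat("collapsed categories in:", paste(names(x$collapsed), collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
logLik.calibration <- function(object, ...) {
  npar <- sum(object$params$n_cat - 1L) +
    if (object$model != "PCM") nrow(object$params) else 0L
  if (object$model == "MIRT2") npar <- npar + 1L
  structure(object$loglik, df = npar, nobs = object$n, class = "logLik")
}
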