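#' Intraclass correlation ICC(A,1)
#'
#' Two-way model, absolute agreement, single measurement (McGraw & Wong's
#' ICC(A,1)): the agreement statistic used to judge whether crosswalk
#' predictions can replace observed scores in group-level analyses. From the
#' two-way mean squares (subjects MSR, raters MSC, error MSE; k raters, n
#' subjects):
#' `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% confidence interval uses the F-distribution interval of the (A,1)
#' estimator with Satterthwaite degrees of freedom. Agreement is flagged
#' adequate for group-level comparisons when the ICC is at least 0.70.
#'
#' @param x,y paired measurement vectors (e.g. observed and predicted scores),
#'   no missing values, n >= 3.
#' @param conf confidence level (default 0.95).
#' @return list of class `icc_a1`: `icc`, `ci` (length-2 vector), `conf`,
#'   `ms` (the mean squares), `n`, `k`, `adequate_group_level`.
#' @examples
#' set.seed(1)
#' x <- rnorm(50); y <- x + rnorm(50, sd = 0.4)
#' icc_a1(x, y)
#' @export
icc_a1 <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("paired vectors of equal length required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  dat <- cbind(x, y)
  k <- 2L
  grand <- mean(dat)
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((dat - outer(row_m, rep(1, k)) -
              matrix(col_m, n, k, byrow = TRUE) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-12 && msc < 1e-12 && mse < 1e-12)
    stop("zero variance in both raters: ICC undefined")
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # F-based CI (McGraw & Wong 1996, Table 7)
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  out <- list(icc = icc, ci = c(lower = lower, upper = upper), conf = conf,
              ms = c(msr = msr, msc = msc, mse = mse), n = n, k = k,
              adequate_group_level = icc >= 0.70)
  class(out) <- "icc_a1"
  out
}

#' @export
print.icc_a1 <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f (%d%% CI %.3f to %.3f), n = %d%s\n",
              x$icc, round(100 * x$conf), x$ci[1], x$ci[2], x$n,
              if (x$adequate_group_level)
                " -- adequate for group-level comparisons (>= 0.70)" else ""))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Differences between paired measurements against their means, with the mean
#' difference and 95% limits of agreement (mean difference +/- 1.96 SD of the
#' differences). The difference convention is observed minus predicted.
#'
#' @param observed,predicted paired score vectors.
#' @return list of class `bland_altman`: `data` (data.frame with `mean` and
#'   `difference` per pair), `mean_diff`, `sd_diff`, `loa` (length-2),
#'   `mean_observed`, `sd_observed`, `mean_predicted`, `sd_predicted`, `n`.
#' @export
bland_altman <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("paired vectors of equal length required")
  ok <- !(is.na(observed) | is.na(predicted))
  observed <- observed[ok]; predicted <- predicted[ok]
  n <- length(observed)
  if (n < 2L) stop("need at least 2 complete pairs")
  d <- observed - predicted
  m <- (observed + predicted) / 2
  md <- mean(d); sd_d <- stats::sd(d)
  out <- list(data = data.frame(mean = m, difference = d),
              mean_diff = md, sd_diff = sd_d,
              loa = c(lower = md - 1.96 * sd_d, upper = md + 1.96 * sd_d),
              mean_observed = mean(observed), sd_observed = stats::sd(observed),
              mean_predicted = mean(predicted),
              sd_predicted = stats::sd(predicted), n = n)
  class(out) <- "bland_altman"
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (observed minus predicted), n = %d\n  observed %.2f (%.2f), predicted %.2f (%.2f)\n  mean difference %.2f (%.2f), LOA %.2f to %.2f\n",
    x$n, x$mean_observed, x$sd_observed, x$mean_predicted, x$sd_predicted,
    x$mean_diff, x$sd_diff, x$loa[1], x$loa[2]))
  invisible(x)
}

#' @rdname bland_altman
#' @param x a `bland_altman` object.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, main = "Bland-Altman", ...) {
  graphics::plot(x$data$mean, x$data$difference,
                 xlab = "Mean of observed and predicted",
                 ylab = "Observed minus predicted", main = main, ...)
  graphics::abline(h = x$mean_diff)
  graphics::abline(h = x$loa, lty = 2)
  invisible(x)
}

#' Four-panel Bland-Altman figure for a crosswalk validation
#'
#' Renders the standard validation figure: agreement panels for HAQ-SDI,
#' HAQ-ADI and the PF-10 predicted from each HAQ scoring method.
#'
#' @param panels named list of `bland_altman` objects (up to 4).
#' @export
plot_agreement_panels <- function(panels) {
  old <- graphics::par(mfrow = c(2, 2))
  on.exit(graphics::par(old))
  for (nm in names(panels)) plot(panels[[nm]], main = nm)
  invisible(panels)
}
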