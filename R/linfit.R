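#' Ordinary least-squares line with one-sided slope inference
#'
#' Fits `y = b0 + b1 * x` by ordinary least squares and reports, for the
#' slope: the standard error, the one-sided lower-tail p-value
#' (`P(T <= t)` with `t = b1 / se`, df = m - 2 — evidence of a *negative*
#' slope), and the symmetric two-sided `(1 - alpha)` confidence interval
#' `b1 +/- t[1 - alpha/2, m - 2] * se`. At the default `alpha = 0.0025`
#' this is the 99.75% interval with bounds at the 0.125% and 99.875%
#' quantiles. This is the statistical engine behind the linear hook
#' detector: a plateau that drifts downward gives a significantly negative
#' tail slope.
#'
#' Edge conventions:
#' * `m = 2` (zero residual df): the slope is exact but `se`, `p` and the
#'   CI are `NA`.
#' * zero-residual data (perfect line, `m > 2`): `se = 0`,
#'   `p = 0` if the slope is negative else `1`, CI collapses to
#'   `[slope, slope]` — a perfect negative line is maximal evidence of a
#'   downward trend.
#'
#' @param x,y Numeric vectors of equal length `m >= 2`; `x` must not be
#'   constant.
#' @param alpha Significance level in (0, 1); the CI level is `1 - alpha`.
#' @return An object of class `tail_lm`: a list with `intercept`, `slope`,
#'   `slope_se`, `p_one_sided`, `ci_low`, `ci_high`, `n_points`,
#'   `start_cycle` (the first x value), `alpha`.
#' @examples
#' fit <- ols_line(1:10, 5 - 0.1 * (1:10))
#' fit$slope
#' @export
ols_line <- function(x, y, alpha = 0.0025) {
  if (length(x) != length(y)) stop("x and y must have equal length.", call. = FALSE)
  m <- length(x)
  if (m < 2) stop("need at least two points.", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1).", call. = FALSE)
  if (diff(range(x)) == 0) stop("degenerate design: x is constant.", call. = FALSE)

  fit <- stats::lm(y ~ x)
  b0 <- unname(stats::coef(fit)[1])
  b1 <- unname(stats::coef(fit)[2])
  df <- m - 2L
  rss <- sum(stats::resid(fit)^2)

  if (df == 0L) {
    se <- NA_real_; p <- NA_real_; lo <- NA_real_; hi <- NA_real_
  } else if (rss <= .Machine$double.eps^0.9 * max(1, sum(y^2))) {
    # perfect line: no residual noise to estimate from; a numerically-zero
    # slope (flat data) is reported as exactly zero so its sign is not a
    # rounding artefact
    if (abs(b1) * diff(range(x)) <= 1e-10 * max(1, max(abs(y)))) b1 <- 0
    se <- 0
    p <- if (b1 < 0) 0 else 1
    lo <- b1; hi <- b1
  } else {
    se <- sqrt(rss / df / sum((x - mean(x))^2))
    p <- stats::pt(b1 / se, df = df)
    half <- stats::qt(1 - alpha / 2, df = df) * se
    lo <- b1 - half; hi <- b1 + half
  }

  structure(
    list(
      intercept = b0, slope = b1, slope_se = se, p_one_sided = p,
      ci_low = lo, ci_high = hi, n_points = m, start_cycle = x[1],
      alpha = alpha
    ),
    class = "tail_lm"
  )
}

#' @export
print.tail_lm <- function(x, ...) {
  cat(sprintf(
    "<tail_lm> slope %.5g (se %.3g), one-sided p %.3g, %.4g%% CI [%.5g, %.5g], n = %d\n",
    x$slope, x$slope_se, x$p_one_sided, 100 * (1 - x$alpha), x$ci_low, x$ci_high,
    x$n_points
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tail regression fit
#'
#' @param x A `tail_lm` object from [ols_line()].
#' @param ... Unused.
#' @return One row per coefficient with estimate, standard error, and for
#'   the slope the one-sided p-value and confidence bounds.
#' @export
tidy.tail_lm <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se),
    p.value = c(NA_real_, x$p_one_sided),
    conf.low = c(NA_real_, x$ci_low),
    conf.high = c(NA_real_, x$ci_high)
  )
}

#' @rdname tidy.tail_lm
#' @return `glance()`: a one-row summary of the fit.
#' @export
glance.tail_lm <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, slope_se = x$slope_se, p_one_sided = x$p_one_sided,
    ci_low = x$ci_low, ci_high = x$ci_high, n_points = x$n_points,
    start_cycle = x$start_cycle, alpha = x$alpha
  )
}
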