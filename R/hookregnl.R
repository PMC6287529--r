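#' Six-parameter log-logistic amplification model
#'
#' Evaluates
#' `y = c + k*x + (d - c) / (1 + exp(b * (log(x) - log(e))))^f`,
#' the standard log-logistic sigmoid extended with a linear drift term
#' `k*x`. Parameters: `c` lower asymptote (baseline), `d` upper asymptote
#' (plateau), `b` sigmoidal slope, `e` point of inflection (exactly, when
#' `f = 1`), `f` asymmetry factor (> 0), `k` per-cycle linear drift.
#' A negative `k` bends the plateau downward — the signature of a hook
#' effect.
#'
#' @param x Cycle values, strictly positive (the model takes `log(x)`).
#' @param b,c,d,e,f,k Model parameters; `e > 0`, `f > 0`.
#' @return Model fluorescence at `x`.
#' @examples
#' l6_model(20, b = -8, c = 0, d = 1, e = 20, f = 1, k = 0) # midpoint: 0.5
#' @export
l6_model <- function(x, b, c, d, e, f, k) {
  if (any(x <= 0)) stop("cycle values must be positive (log-logistic model).", call. = FALSE)
  if (e <= 0) stop("`e` must be positive.", call. = FALSE)
  if (f <= 0) stop("`f` must be positive.", call. = FALSE)
  c + k * x + (d - c) / (1 + exp(b * (log(x) - log(e))))^f
}

l6_start <- function(x, y, b0) {
  gains <- diff(y)
  e0 <- x[which.max(gains)]
  e0 <- min(max(e0, min(x) + 1e-6), max(x) - 1e-6)
  list(b = b0, c = min(y), d = max(y), e = e0, f = 1, k = 0)
}

#' Fit the six-parameter log-logistic model to one amplification curve
#'
#' Trims the first `trim` baseline cycles (a sloping ground phase
#' otherwise leaks into the drift term `k` and causes false positives),
#' normalizes fluorescence to the 99th percentile, and estimates
#' `(b, c, d, e, f, k)` by Levenberg-Marquardt nonlinear least squares with
#' bounds `f > 0` and `e` inside the observed cycle range. The standard
#' error of `k` comes from the Jacobian-based covariance; its
#' `(1 - alpha)` confidence interval uses the t distribution with
#' `m - 6` degrees of freedom. Starting values are sigmoid heuristics
#' (`c = min`, `d = max`, `e` at the steepest single-cycle gain, `f = 1`,
#' `k = 0`); on failure the sigmoidal slope is restarted at -5 and -20.
#'
#' @param curve A single-well [amp_curves()] table (or any data frame with
#'   `cycle` and `fluorescence`).
#' @param trim Number of leading baseline cycles to drop (default 5,
#'   increase for long baselines).
#' @param alpha Significance level for the CI of `k` (default 0.0025).
#' @param normalize Normalize fluorescence before fitting (default TRUE);
#'   the hook decision is scale-invariant either way.
#' @return An object of class `l6_fit`: parameter estimates, `k_se`,
#'   `k_ci_low`, `k_ci_high`, `converged`, `rss`, `n_points`, plus the
#'   trimmed data and fitted values for inspection. When fewer than 12
#'   points remain after trimming, or the optimizer or covariance fails,
#'   `converged` is `FALSE` and the inference fields are `NA`.
#' @export
fit_l6 <- function(curve, trim = 5, alpha = 0.0025, normalize = TRUE) {
  x_all <- curve$cycle
  y_all <- curve$fluorescence
  keep <- seq_along(x_all) > trim
  x <- x_all[keep]
  y <- y_all[keep]
  failed <- function(status) {
    structure(
      list(
        b = NA_real_, c = NA_real_, d = NA_real_, e = NA_real_, f = NA_real_,
        k = NA_real_, k_se = NA_real_, k_ci_low = NA_real_, k_ci_high = NA_real_,
        converged = FALSE, rss = NA_real_, n_points = length(x),
        alpha = alpha, status = status, data = tibble::tibble(cycle = x, fluorescence = y),
        fitted = NULL
      ),
      class = "l6_fit"
    )
  }
  if (length(x) < 12) return(failed("insufficient_data"))
  if (any(x <= 0)) stop("cycle values must be positive.", call. = FALSE)
  if (normalize) {
    if (diff(range(y)) == 0) return(failed("fit_failed"))
    y <- normalize_fluor(y)
  }

  dat <- data.frame(x = x, y = y)
  lower <- c(b = -Inf, c = -Inf, d = -Inf, e = min(x), f = 1e-6, k = -Inf)
  upper <- c(b = Inf, c = Inf, d = Inf, e = max(x), f = Inf, k = Inf)
  # Multi-start: the 6-parameter surface has local minima (notably for
  # truncated sigmoids whose inflection sits near the last cycle), so all
  # starts are tried and the lowest-RSS fit kept.
  fit <- NULL
  fit_rss <- Inf
  for (b0 in c(-10, -5, -20)) {
    start <- l6_start(x, y, b0)
    cand <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ c + k * x + (d - c) / (1 + exp(b * (log(x) - log(e))))^f,
        data = dat, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 1000, maxfev = 1000, ftol = 1e-8)
      )),
      error = function(e) NULL
    )
    if (!is.null(cand)) {
      cand_rss <- sum(stats::resid(cand)^2)
      if (cand_rss < fit_rss) {
        fit <- cand
        fit_rss <- cand_rss
      }
    }
  }
  if (is.null(fit)) return(failed("fit_failed"))

  est <- as.list(stats::coef(fit))
  rss <- sum(stats::resid(fit)^2)
  df <- length(x) - 6L
  scale2 <- max(1, sum(y^2))
  if (rss <= .Machine$double.eps^(2 / 3) * scale2) {
    # Exact fit: the data sit on the model surface to machine precision, so
    # the residual-based covariance carries no information and the optimizer's
    # stopping error dominates the estimate of k. Report k to numerical
    # precision (|k| below 1e-8 on the normalized scale is numerical zero)
    # with a point CI — the analogue of the perfect-line convention in
    # ols_line().
    k_hat <- est$k
    if (abs(k_hat) < 1e-8 * sqrt(scale2 / length(y))) k_hat <- 0
    est$k <- k_hat
    k_se <- 0
    half <- 0
  } else {
    k_se <- tryCatch(sqrt(diag(stats::vcov(fit))[["k"]]), error = function(e) NA_real_)
    if (!is.finite(k_se)) return(failed("fit_failed"))
    half <- stats::qt(1 - alpha / 2, df = df) * k_se
  }
  structure(
    list(
      b = est$b, c = est$c, d = est$d, e = est$e, f = est$f, k = est$k,
      k_se = k_se, k_ci_low = est$k - half, k_ci_high = est$k + half,
      converged = TRUE, rss = rss, n_points = length(x), alpha = alpha,
      status = "ok",
      data = tibble::tibble(cycle = x, fluorescence = y),
      fitted = unname(stats::fitted(fit))
    ),
    class = "l6_fit"
  )
}

#' @export
print.l6_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<l6_fit> not converged (", x$status, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<l6_fit> b %.3g, c %.3g, d %.3g, e %.3g, f %.3g | k %.4g, %.4g%% CI [%.4g, %.4g]\n",
    x$b, x$c, x$d, x$e, x$f, x$k, 100 * (1 - x$alpha), x$k_ci_low, x$k_ci_high
  ))
  invisible(x)
}

#' Tidy a six-parameter log-logistic fit
#'
#' @param x An `l6_fit` from [fit_l6()].
#' @param ... Unused.
#' @return `tidy()`: one row per parameter; the drift `k` carries its
#'   standard error and confidence bounds. `glance()`: a one-row fit
#'   summary.
#' @export
tidy.l6_fit <- function(x, ...) {
  tibble::tibble(
    term = c("b", "c", "d", "e", "f", "k"),
    estimate = c(x$b, x$c, x$d, x$e, x$f, x$k),
    std.error = c(rep(NA_real_, 5), x$k_se),
    conf.low = c(rep(NA_real_, 5), x$k_ci_low),
    conf.high = c(rep(NA_real_, 5), x$k_ci_high)
  )
}

#' @rdname tidy.l6_fit
#' @export
glance.l6_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, k_se = x$k_se, k_ci_low = x$k_ci_low, k_ci_high = x$k_ci_high,
    converged = x$converged, rss = x$rss, n_points = x$n_points,
    status = x$status
  )
}

hookregnl_one <- function(df, trim, alpha, snr_min) {
  w <- df$well_id[1]
  y <- df$fluorescence
  if (length(y) >= 10 && is_negative_reaction(y, snr_min = snr_min)) {
    return(hook_call_row(w, "hookregNL", status = "negative_reaction"))
  }
  fit <- fit_l6(df, trim = trim, alpha = alpha)
  if (!fit$converged) {
    return(hook_call_row(w, "hookregNL", status = "fit_failed"))
  }
  hook_call_row(
    w, "hookregNL",
    hook = fit$k_ci_high < 0 && fit$k_ci_low < 0,
    slope = fit$k, ci_low = fit$k_ci_low, ci_high = fit$k_ci_high,
    status = "ok"
  )
}

#' Nonlinear (log-logistic) hook detector
#'
#' For each well: discard negative reactions (same gate as [hookreg()]),
#' then fit the six-parameter log-logistic model with [fit_l6()] and call
#' a hook when both bounds of the `(1 - alpha)` confidence interval of the
#' linear drift `k` are negative — i.e. zero drift is confidently
#' excluded. No p-value is reported; the decision is interval-based.
#' Non-convergence yields `status = "fit_failed"` and `hook = FALSE`
#' rather than an error, so plate-scale batches never abort.
#'
#' @inheritParams hookreg
#' @param trim Leading baseline cycles removed before fitting (default 5).
#' @return A call tibble with the same columns as [hookreg()]; `p_value`
#'   and `hook_start_cycle` are `NA` for this method.
#' @examples
#' plate <- simulate_plate(n_per_class = 2, seed = 1)
#' hookregnl(plate$curves)
#' @export
hookregnl <- function(curves, trim = 5, alpha = 0.0025, snr_min = 10) {
  curves <- amp_curves(curves)
  purrr::list_rbind(lapply(
    split_wells(curves), hookregnl_one,
    trim = trim, alpha = alpha, snr_min = snr_min
  ))
}
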