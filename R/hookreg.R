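#' Locate the fluorescence maximum of a curve
#'
#' Returns the cycle at which fluorescence attains its maximum; ties are
#' broken by the earliest such cycle, which maximizes the length of the
#' tail available for regression.
#'
#' @param cycle,fluorescence Numeric vectors for one well.
#' @return The cycle value (not index) of the maximum.
#' @export
find_max_cycle <- function(cycle, fluorescence) {
  if (length(cycle) == 0) stop("empty curve.", call. = FALSE)
  cycle[which.max(fluorescence)]
}

#' Normalize fluorescence to the 99th percentile
#'
#' Shifts a fluorescence series to zero minimum and scales it by the 99th
#' percentile of the shifted series (linear-interpolation percentile, the
#' default `stats::quantile()` type 7). The maximum therefore lands
#' slightly above 1. Normalization does not change which cycle holds the
#' maximum, so the hook decision is unaffected; it standardizes the scale
#' on which slopes are reported.
#'
#' @param fluorescence Numeric vector.
#' @return Normalized vector, or an error for a flat series (the
#'   negative-reaction gate is expected to catch those first).
#' @export
normalize_fluor <- function(fluorescence) {
  shifted <- fluorescence - min(fluorescence)
  q99 <- unname(stats::quantile(shifted, 0.99, names = FALSE))
  if (q99 <= 0) stop("degenerate signal: flat curve cannot be normalized.", call. = FALSE)
  shifted / q99
}

#' Flag negative (no-amplification) reactions
#'
#' A reaction is called negative when its signal-to-noise ratio —
#' total amplitude `max(y) - min(y)` divided by the standard deviation of
#' the first ten cycles (the ground phase) — falls below `snr_min`.
#' Negative reactions carry no plateau to interrogate and are excluded
#' from hook calling rather than risking spurious tail fits.
#'
#' A zero ground-phase standard deviation with positive amplitude counts
#' as infinite SNR (not negative); an entirely flat curve is negative.
#'
#' @param fluorescence Numeric vector of at least 10 readings.
#' @param snr_min Amplitude-to-noise threshold below which the reaction is
#'   deemed negative (default 10).
#' @return Logical scalar.
#' @export
is_negative_reaction <- function(fluorescence, snr_min = 10) {
  if (length(fluorescence) < 10) stop("need at least 10 cycles for the noise estimate.", call. = FALSE)
  amplitude <- max(fluorescence) - min(fluorescence)
  if (amplitude == 0) return(TRUE)
  noise <- stats::sd(fluorescence[1:10])
  if (noise == 0) return(FALSE)
  amplitude / noise < snr_min
}

# Empty call-table prototype; every detector returns rows of this shape.
hook_call_row <- function(well_id, method, hook = FALSE, slope = NA_real_,
                          p_value = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, hook_start_cycle = NA_real_,
                          status = "ok") {
  tibble::tibble(
    well_id = well_id, method = method, hook = hook, slope = slope,
    p_value = p_value, ci_low = ci_low, ci_high = ci_high,
    hook_start_cycle = hook_start_cycle, status = status
  )
}

hookreg_one <- function(df, alpha, min_tail, snr_min) {
  w <- df$well_id[1]
  y <- df$fluorescence
  x <- df$cycle
  if (length(y) >= 10 && is_negative_reaction(y, snr_min = snr_min)) {
    return(hook_call_row(w, "hookreg", status = "negative_reaction"))
  }
  if (diff(range(y)) == 0) {
    return(hook_call_row(w, "hookreg", status = "negative_reaction"))
  }
  yn <- normalize_fluor(y)
  x0 <- find_max_cycle(x, yn)
  tail_idx <- which(x >= x0)
  if (length(tail_idx) - 1L < min_tail) {
    return(hook_call_row(w, "hookreg",
      hook_start_cycle = x0, status = "insufficient_tail"
    ))
  }
  fit <- ols_line(x[tail_idx], yn[tail_idx], alpha = alpha)
  sig_p <- !is.na(fit$p_one_sided) && fit$p_one_sided < alpha
  sig_ci <- !is.na(fit$ci_high) && fit$ci_high < 0 && fit$ci_low < 0
  hook_call_row(
    w, "hookreg",
    hook = sig_p || sig_ci, slope = fit$slope, p_value = fit$p_one_sided,
    ci_low = fit$ci_low, ci_high = fit$ci_high, hook_start_cycle = x0,
    status = "ok"
  )
}

#' Linear hook detector
#'
#' For each well: (1) discard negative reactions via the signal-to-noise
#' gate; (2) normalize fluorescence to the 99th percentile; (3) find the
#' cycle of maximum fluorescence `x0`; (4) require at least `min_tail`
#' additional cycles after `x0`, otherwise the tail is too short to
#' regress; (5) fit an ordinary least-squares line to cycles `x0..xn`;
#' (6) call a hook when the slope is significantly negative — one-sided
#' `p < alpha`, or the whole `(1 - alpha)` confidence interval below zero.
#'
#' @param curves An [amp_curves()] table (any number of wells).
#' @param alpha Significance level for the one-sided slope test and the CI
#'   (default 0.0025, i.e. a 99.75% interval).
#' @param min_tail Minimum number of cycles required *after* the maximum
#'   (default 5).
#' @param snr_min Negative-reaction gate threshold, see
#'   [is_negative_reaction()].
#' @return A tibble with one row per well: `well_id`, `method`, `hook`,
#'   `slope`, `p_value`, `ci_low`, `ci_high`, `hook_start_cycle`, `status`
#'   (`ok`, `insufficient_tail`, `negative_reaction` or `fit_failed`).
#'   `hook = TRUE` only ever occurs with `status = "ok"`.
#' @examples
#' plate <- simulate_plate(n_per_class = 2, seed = 1)
#' hookreg(plate$curves)
#' @export
hookreg <- function(curves, alpha = 0.0025, min_tail = 5, snr_min = 10) {
  curves <- amp_curves(curves)
  purrr::list_rbind(lapply(
    split_wells(curves), hookreg_one,
    alpha = alpha, min_tail = min_tail, snr_min = snr_min
  ))
}
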