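#' Combine linear and nonlinear hook calls
#'
#' The two detectors are complementary: the linear tail regression is
#' sensitive to pronounced hooks with a clear post-maximum decline, while
#' the log-logistic fit picks up slight plateau drifts that never produce
#' an early maximum. Their disjunction (logical OR) is the package's final
#' classifier: a well is hook-positive when either detector calls it.
#'
#' @param linear Call tibble from [hookreg()].
#' @param nonlinear Call tibble from [hookregnl()] over the same wells.
#' @return A call tibble with `method = "combined"`, `hook` the OR of the
#'   two decisions, `status = "ok"` when either input is ok, and the two
#'   slope estimates carried along as `slope_hookreg` / `slope_hookregnl`
#'   provenance columns (`slope` itself is the linear estimate when
#'   available, otherwise the drift `k`).
#' @examples
#' plate <- simulate_plate(n_per_class = 2, seed = 1)
#' combine_calls(hookreg(plate$curves), hookregnl(plate$curves))
#' @export
combine_calls <- function(linear, nonlinear) {
  if (!setequal(linear$well_id, nonlinear$well_id) ||
      nrow(linear) != nrow(nonlinear)) {
    stop("the two call sets must cover exactly the same wells.", call. = FALSE)
  }
  a <- dplyr::arrange(linear, .data$well_id)
  b <- dplyr::arrange(nonlinear, .data$well_id)
  tibble::tibble(
    well_id = a$well_id,
    method = "combined",
    hook = a$hook | b$hook,
    slope = dplyr::coalesce(a$slope, b$slope),
    p_value = a$p_value,
    ci_low = dplyr::coalesce(a$ci_low, b$ci_low),
    ci_high = dplyr::coalesce(a$ci_high, b$ci_high),
    hook_start_cycle = a$hook_start_cycle,
    status = ifelse(a$status == "ok" | b$status == "ok", "ok",
      ifelse(a$status == b$status, a$status, "fit_failed")
    ),
    slope_hookreg = a$slope,
    slope_hookregnl = b$slope
  )
}

#' Run hook detection on a plate
#'
#' One-stop wrapper: runs the requested detector(s) over every well and
#' returns a single tidy call table.
#'
#' @inheritParams hookreg
#' @param method `"combined"` (default; runs both detectors and ORs them),
#'   `"hookreg"` or `"hookregnl"`.
#' @param trim Baseline cycles removed by the nonlinear detector.
#' @return A call tibble, one row per well (see [hookreg()] for columns).
#' @examples
#' plate <- simulate_plate(n_per_class = 2, seed = 7)
#' hook_calls(plate$curves, method = "combined")
#' @export
hook_calls <- function(curves, method = c("combined", "hookreg", "hookregnl"),
                       alpha = 0.0025, min_tail = 5, trim = 5, snr_min = 10) {
  method <- match.arg(method)
  curves <- amp_curves(curves)
  switch(method,
    hookreg = hookreg(curves, alpha = alpha, min_tail = min_tail, snr_min = snr_min),
    hookregnl = hookregnl(curves, trim = trim, alpha = alpha, snr_min = snr_min),
    combined = combine_calls(
      hookreg(curves, alpha = alpha, min_tail = min_tail, snr_min = snr_min),
      hookregnl(curves, trim = trim, alpha = alpha, snr_min = snr_min)
    )
  )
}
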