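#' Benchmark hook calls against human labels
#'
#' Crosses boolean calls with curve-level truth labels (positive class =
#' hook) and computes the confusion counts and the five standard
#' classifier metrics: sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' false positive rate `fp/(fp+tn)`, false negative rate `fn/(fn+tp)` and
#' accuracy `(tp+tn)/n`. Metrics with a zero denominator are `NA`, never
#' silently 0. Values are stored at full precision; round only for display
#' (see [format_performance()]).
#'
#' @param calls A call tibble (from [hookreg()], [hookregnl()],
#'   [hook_calls()], or several row-bound together — the `method` column
#'   groups the evaluation).
#' @param labels A data frame with `well_id` and `label`
#'   (`"hook"`/`"no_hook"`), e.g. from [read_labels()].
#' @return A tibble with one row per method: `method`, `tp`, `tn`, `fp`,
#'   `fn`, `sensitivity`, `specificity`, `fpr`, `fnr`, `accuracy`.
#' @examples
#' plate <- simulate_plate(n_per_class = 3, seed = 2)
#' evaluate_calls(hook_calls(plate$curves), plate$labels)
#' @export
evaluate_calls <- function(calls, labels) {
  labels <- tibble::as_tibble(labels)
  missing_wells <- setdiff(unique(calls$well_id), labels$well_id)
  if (length(missing_wells) > 0) {
    stop(
      "no label for well(s): ", paste(sort(missing_wells), collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(labels$label), c("hook", "no_hook"))
  if (length(bad) > 0) {
    stop("labels must be 'hook' or 'no_hook'.", call. = FALSE)
  }
  dplyr::inner_join(calls, labels, by = "well_id") |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      tp = sum(.data$hook & .data$label == "hook"),
      tn = sum(!.data$hook & .data$label == "no_hook"),
      fp = sum(.data$hook & .data$label == "no_hook"),
      fn = sum(!.data$hook & .data$label == "hook"),
      .groups = "drop"
    ) |>
    dplyr::mutate(performance_metrics(.data$tp, .data$tn, .data$fp, .data$fn))
}

#' Confusion-matrix metrics from raw counts
#'
#' @param tp,tn,fp,fn Non-negative counts (vectorized).
#' @return A tibble with `sensitivity`, `specificity`, `fpr`, `fnr`,
#'   `accuracy`; ratios with zero denominator are `NA`.
#' @export
performance_metrics <- function(tp, tn, fp, fn) {
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble::tibble(
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    fpr = safe_div(fp, fp + tn),
    fnr = safe_div(fn, fn + tp),
    accuracy = safe_div(tp + tn, tp + tn + fp + fn)
  )
}

#' Format a performance table for display
#'
#' Rounds the five metrics to two decimals (counts untouched), the
#' customary precision for reporting classifier benchmarks.
#'
#' @param perf Output of [evaluate_calls()].
#' @param digits Decimal places (default 2).
#' @return The tibble with rounded metric columns.
#' @export
format_performance <- function(perf, digits = 2) {
  dplyr::mutate(perf, dplyr::across(
    dplyr::any_of(c("sensitivity", "specificity", "fpr", "fnr", "accuracy")),
    ~ round(.x, digits)
  ))
}
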