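#' Plot amplification curves
#'
#' Draws every well's trace; when a call table is supplied, traces are
#' coloured by the hook decision, the way benchmark plates are usually
#' displayed.
#'
#' @param object An [amp_curves()] table.
#' @param calls Optional call tibble (from [hook_calls()] and friends) to
#'   colour by decision.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot.amp_curves
#' @export
autoplot.amp_curves <- function(object, calls = NULL, ...) {
  dat <- tibble::as_tibble(object)
  if (!is.null(calls)) {
    dat <- dplyr::left_join(
      dat, dplyr::select(calls, "well_id", "hook"),
      by = "well_id"
    ) |>
      dplyr::mutate(hook = ifelse(.data$hook, "hook", "no hook"))
    p <- ggplot2::ggplot(dat, ggplot2::aes(
      .data$cycle, .data$fluorescence,
      group = .data$well_id, colour = .data$hook
    )) +
      ggplot2::scale_colour_manual(
        values = c("hook" = "#c0392b", "no hook" = "grey30"),
        name = NULL
      )
  } else {
    p <- ggplot2::ggplot(dat, ggplot2::aes(
      .data$cycle, .data$fluorescence,
      group = .data$well_id
    ))
  }
  p +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "cycle", y = "fluorescence (RFU)") +
    ggplot2::theme_minimal()
}

#' Plot a six-parameter log-logistic fit
#'
#' Observed (normalized) readings with the fitted curve overlaid.
#'
#' @param object An `l6_fit` from [fit_l6()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export autoplot.l6_fit
#' @export
autoplot.l6_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$cycle, .data$fluorescence)) +
    ggplot2::geom_point(size = 1, colour = "grey40") +
    ggplot2::labs(x = "cycle", y = "normalized fluorescence") +
    ggplot2::theme_minimal()
  if (object$converged) {
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(cycle = object$data$cycle, fluorescence = object$fitted),
      colour = "#c0392b"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
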