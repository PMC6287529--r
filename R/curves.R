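#' Amplification curve tables
#'
#' `hookdetect` represents a plate of qPCR amplification curves as a long
#' tibble with one row per (well, cycle) reading and class `amp_curves`:
#'
#' * `well_id`      — well/trace label, e.g. `"A01"` (character)
#' * `sample_name`  — sample annotation (character, may be `NA`)
#' * `detector`     — dye/probe chemistry label (character, may be `NA`)
#' * `cycle`        — PCR cycle index, strictly increasing within a well
#' * `fluorescence` — raw instrument readout (RFU), finite
#'
#' `amp_curves()` validates a data frame against this contract and attaches
#' the class; readers and the simulator return such tables, and every
#' detector accepts one as its first argument, so calls chain with the pipe.
#'
#' @param data A data frame with at least `well_id`, `cycle` and
#'   `fluorescence` columns. `sample_name` and `detector` are added as `NA`
#'   when absent.
#' @return A tibble of class `amp_curves`.
#' @examples
#' amp_curves(data.frame(well_id = "A01", cycle = 1:5, fluorescence = 1:5))
#' @export
amp_curves <- function(data) {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame of per-cycle fluorescence readings.", call. = FALSE)
  }
  need <- c("well_id", "cycle", "fluorescence")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  if (!"sample_name" %in% names(out)) out$sample_name <- NA_character_
  if (!"detector" %in% names(out)) out$detector <- NA_character_
  out <- dplyr::select(
    out, "well_id", "sample_name", "detector", "cycle", "fluorescence",
    dplyr::everything()
  )
  out$well_id <- as.character(out$well_id)
  out$cycle <- as.numeric(out$cycle)
  out$fluorescence <- as.numeric(out$fluorescence)
  validate_amp_curves(out)
  class(out) <- unique(c("amp_curves", class(out)))
  out
}

validate_amp_curves <- function(data) {
  if (nrow(data) == 0) return(invisible(data))
  if (anyNA(data$well_id)) stop("`well_id` must not contain NA.", call. = FALSE)
  bad_fluor <- !is.finite(data$fluorescence)
  if (any(bad_fluor)) {
    w <- unique(data$well_id[bad_fluor])
    stop("non-finite fluorescence in well(s): ", paste(w, collapse = ", "), call. = FALSE)
  }
  not_incr <- data |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(ok = all(diff(.data$cycle) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(not_incr) > 0) {
    stop(
      "cycles must be strictly increasing within each well; offending well(s): ",
      paste(not_incr$well_id, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(data)
}

#' Split an amplification table into one tibble per well
#'
#' @param curves An [amp_curves()] table.
#' @return A named list of single-well tibbles, names are `well_id`s in
#'   lexicographic order (the package's stable processing order).
#' @keywords internal
split_wells <- function(curves) {
  wells <- sort(unique(curves$well_id))
  lapply(stats::setNames(wells, wells), function(w) {
    dplyr::filter(curves, .data$well_id == w)
  })
}

#' Curve-level truth labels
#'
#' A labelled curve set pairs an [amp_curves()] table with a label tibble
#' (`well_id`, `label` in `"hook"`/`"no_hook"`) as produced by a human rater.
#'
#' @param curves An [amp_curves()] table.
#' @param labels A data frame with columns `well_id` and `label`
#'   (values `"hook"` or `"no_hook"`).
#' @return A list of class `labelled_curves` with elements `curves`, `labels`.
#' @export
labelled_curves <- function(curves, labels) {
  curves <- amp_curves(curves)
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("well_id", "label") %in% names(labels)))
  bad <- setdiff(labels$label, c("hook", "no_hook"))
  if (length(bad) > 0) {
    stop("labels must be 'hook' or 'no_hook'; got: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  orphans <- setdiff(labels$well_id, unique(curves$well_id))
  if (length(orphans) > 0) {
    stop("label(s) with no matching curve: ", paste(orphans, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(labels$well_id)) {
    stop("duplicate well_id in labels.", call. = FALSE)
  }
  structure(list(curves = curves, labels = labels), class = "labelled_curves")
}

#' @export
print.labelled_curves <- function(x, ...) {
  cat(
    "<labelled_curves> ", dplyr::n_distinct(x$curves$well_id), " curves, ",
    sum(x$labels$label == "hook"), " labelled hook\n",
    sep = ""
  )
  invisible(x)
}
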