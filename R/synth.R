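# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one amplification curve
#'
#' Generates a synthetic qPCR trace from the six-parameter log-logistic
#' model plus homoscedastic Gaussian noise:
#' `y_i = l6_model(x_i) + N(0, noise_sd^2)`. Four shapes cover the
#' curve classes seen on real plates:
#'
#' * `"sigmoid"` — regular amplification, flat plateau (`drift = 0`).
#' * `"hook"` — plateau with a negative linear drift (`drift < 0`); the
#'   truth label is `hook`.
#' * `"no_plateau"` — amplification still rising at the last cycle
#'   (midpoint forced beyond 90% of the run), so no plateau to interrogate.
#' * `"negative"` — failed reaction: baseline plus noise, zero amplitude.
#'
#' @param shape One of `"sigmoid"`, `"hook"`, `"no_plateau"`, `"negative"`.
#' @param n_cycles Number of cycles (default 45).
#' @param baseline Lower asymptote `c` (RFU).
#' @param amplitude Plateau rise `d - c` (RFU); ignored (zero) for
#'   `"negative"`.
#' @param midpoint Inflection location `e` in cycles.
#' @param steepness Sigmoidal slope `b` (negative for rising curves).
#' @param asymmetry Asymmetry factor `f > 0`.
#' @param drift Per-cycle linear term `k`; must be negative for
#'   `"hook"`.
#' @param noise_sd Gaussian noise standard deviation (RFU).
#' @param seed Optional integer; when given the curve is reproducible and
#'   the caller's RNG state is left untouched.
#' @param well_id Label for the generated well.
#' @return A list with `curve` (an [amp_curves()] tibble) and `label`
#'   (`"hook"` or `"no_hook"`).
#' @examples
#' sim <- simulate_curve("hook", drift = -0.01, noise_sd = 0, seed = 1)
#' sim$label
#' @export
simulate_curve <- function(shape = c("sigmoid", "hook", "no_plateau", "negative"),
                           n_cycles = 45, baseline = 0.1, amplitude = 1,
                           midpoint = 22, steepness = -10, asymmetry = 1,
                           drift = 0, noise_sd = 0, seed = NULL,
                           well_id = "S01") {
  shape <- match.arg(shape)
  if (shape == "hook" && drift >= 0) {
    stop("`shape = \"hook\"` requires a negative `drift`.", call. = FALSE)
  }
  if (shape == "negative") amplitude <- 0
  if (shape == "no_plateau") midpoint <- max(midpoint, 0.92 * n_cycles)
  x <- seq_len(n_cycles)
  mu <- if (shape == "negative") {
    rep(baseline, n_cycles)
  } else {
    l6_model(
      x, b = steepness, c = baseline, d = baseline + amplitude,
      e = midpoint, f = asymmetry, k = drift
    )
  }
  eps <- with_seed(seed, stats::rnorm(n_cycles, sd = noise_sd))
  curve <- amp_curves(tibble::tibble(
    well_id = well_id, sample_name = shape, detector = "synthetic",
    cycle = as.numeric(x), fluorescence = mu + eps
  ))
  label <- if (shape == "hook" && drift < 0) "hook" else "no_hook"
  list(curve = curve, label = label)
}

# Parameter ranges for randomized plates; chosen to span the curve
# geometries seen on real instruments (documented in the methods vignette).
synth_ranges <- list(
  baseline = c(0, 0.2),
  amplitude = c(0.5, 3),
  # hook effects arise at high template concentration, i.e. in strong-signal
  # reactions, so hook-class curves draw from the upper amplitude range
  amplitude_hook = c(1.5, 3),
  midpoint = c(15, 25),
  steepness = c(-15, -5),
  asymmetry = c(0.5, 2),
  drift_slight = c(-0.01, -0.005),
  drift_pronounced = c(-0.03, -0.015)
)

#' Simulate a labelled benchmark plate
#'
#' Draws a balanced plate over five curve classes — regular sigmoids,
#' negative reactions, curves with no plateau phase, slight negative
#' plateau trends (hook effect-like) and pronounced hook effects — with
#' parameters randomized within documented ranges. The two hook classes
#' carry the truth label `hook`.
#'
#' @param n_per_class Curves per class (plate size = 5x this).
#' @param noise_sd Gaussian noise level shared by all curves (default
#'   0.005 normalized RFU on unit-scale amplitudes).
#' @param n_cycles Cycles per curve (default 45).
#' @param seed Integer seed; the plate is fully reproducible.
#' @return A [labelled_curves()] list: `curves` (an [amp_curves()] table)
#'   and `labels` (`well_id`, `label`).
#' @examples
#' plate <- simulate_plate(n_per_class = 5, seed = 1)
#' table(plate$labels$label)
#' @export
simulate_plate <- function(n_per_class, noise_sd = 0.005, n_cycles = 45, seed = 1) {
  stopifnot(n_per_class >= 1)
  classes <- c("sigmoid", "negative", "no_plateau", "hook_slight", "hook_pronounced")
  with_seed(seed, {
    specs <- tidyr::expand_grid(class = classes, rep = seq_len(n_per_class))
    n <- nrow(specs)
    r <- synth_ranges
    runifr <- function(rg) stats::runif(n, rg[1], rg[2])
    specs <- dplyr::mutate(
      specs,
      well_id = sprintf("W%03d", seq_len(n)),
      baseline = runifr(r$baseline),
      amplitude = ifelse(
        grepl("^hook", class), runifr(r$amplitude_hook), runifr(r$amplitude)
      ),
      midpoint = runifr(r$midpoint),
      steepness = runifr(r$steepness),
      asymmetry = runifr(r$asymmetry),
      drift = dplyr::case_when(
        class == "hook_slight" ~ runifr(r$drift_slight),
        class == "hook_pronounced" ~ runifr(r$drift_pronounced),
        TRUE ~ 0
      ),
      shape = dplyr::case_when(
        class %in% c("hook_slight", "hook_pronounced") ~ "hook",
        TRUE ~ class
      )
    )
    sims <- purrr::pmap(
      dplyr::select(
        specs, "shape", "well_id", "baseline", "amplitude", "midpoint",
        "steepness", "asymmetry", "drift"
      ),
      function(shape, well_id, baseline, amplitude, midpoint, steepness,
               asymmetry, drift) {
        simulate_curve(
          shape = shape, n_cycles = n_cycles, baseline = baseline,
          amplitude = amplitude, midpoint = midpoint, steepness = steepness,
          asymmetry = asymmetry, drift = drift, noise_sd = noise_sd,
          seed = NULL, well_id = well_id
        )
      }
    )
    curves <- amp_curves(purrr::list_rbind(purrr::map(sims, "curve")))
    labels <- tibble::tibble(
      well_id = specs$well_id,
      label = purrr::map_chr(sims, "label")
    )
    labelled_curves(curves, labels)
  })
}
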