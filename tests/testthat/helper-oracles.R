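# Independent textbook-formula oracle for simple linear regression:
# normal equations, residual-variance standard error, lower-tail t test,
# symmetric CI. Kept free of any package code so it can arbitrate ols_line().
ols_oracle <- function(x, y, alpha = 0.0025) {
  m <- length(x)
  xbar <- mean(x)
  ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  b1 <- sum((x - xbar) * (y - ybar)) / sxx
  b0 <- ybar - b1 * xbar
  res <- y - b0 - b1 * x
  s2 <- sum(res^2) / (m - 2)
  se <- sqrt(s2 / sxx)
  tq <- qt(1 - alpha / 2, df = m - 2)
  list(
    intercept = b0, slope = b1, se = se,
    p = pt(b1 / se, df = m - 2),
    ci_low = b1 - tq * se, ci_high = b1 + tq * se
  )
}

# Direct transcription of the six-parameter log-logistic formula, written
# out without reusing package code.
l6_direct <- function(x, b, c, d, e, f, k) {
  c + k * x + (d - c) / (1 + exp(b * (log(x) - log(e))))^f
}

# Piecewise plateau-decline curve: sigmoid rising to a flat plateau at
# `peak_cycle`, then a linear decline. Built independently of the l6
# simulator so hookreg can be checked against a known tail slope.
piecewise_hook_curve <- function(n_cycles = 45, peak_cycle = 30, decline = 0.01,
                                 noise_sd = 0, seed = NULL, well_id = "P01") {
  x <- seq_len(n_cycles)
  rise <- 1 / (1 + exp(-0.6 * (x - 15)))
  y <- ifelse(x <= peak_cycle, rise, rise[peak_cycle] - decline * (x - peak_cycle))
  if (!is.null(seed)) set.seed(seed)
  y <- y + rnorm(n_cycles, sd = noise_sd)
  amp_curves(tibble::tibble(well_id = well_id, cycle = as.numeric(x), fluorescence = y))
}

random_labelled_calls <- function(n, seed) {
  set.seed(seed)
  wells <- sprintf("R%03d", seq_len(n))
  list(
    calls = tibble::tibble(
      well_id = wells, method = "m", hook = sample(c(TRUE, FALSE), n, replace = TRUE),
      slope = NA_real_, p_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      hook_start_cycle = NA_real_, status = "ok"
    ),
    labels = tibble::tibble(
      well_id = wells,
      label = sample(c("hook", "no_hook"), n, replace = TRUE)
    )
  )
}
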