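test_that("find_max_cycle takes the earliest maximum", {
  expect_equal(find_max_cycle(1:40, 1:40), 40) # monotone rise
  expect_equal(find_max_cycle(1:10, rep(3, 10)), 1) # constant: earliest tie
  expect_equal(find_max_cycle(1:5, c(1, 9, 9, 2, 1)), 2) # tie broken early

  set.seed(33)
  for (i in 1:50) {
    y <- rnorm(40)
    x <- seq_len(40)
    brute <- x[min(which(y == max(y)))] # exhaustive scan
    expect_equal(find_max_cycle(x, y), brute)
  }
  expect_error(find_max_cycle(numeric(), numeric()), "empty")
})

test_that("normalization anchors the 99th percentile at 1", {
  # 100 equally spaced points spanning [0, 100]: q99 (type 7) is 99, so the
  # maximum lands at 100/99
  y <- seq(0, 100, length.out = 100)
  yn <- normalize_fluor(y)
  expect_equal(max(yn), 100 / 99, tolerance = 1e-12)
  expect_equal(min(yn), 0)

  # idempotence up to numerical precision
  expect_equal(normalize_fluor(yn), yn, tolerance = 1e-12)

  # order of the maximum is unchanged
  set.seed(12)
  y <- cumsum(rnorm(50))
  expect_equal(which.max(normalize_fluor(y)), which.max(y))

  expect_error(normalize_fluor(rep(5, 20)), "flat")
})

test_that("the negative-reaction gate separates noise from amplification", {
  set.seed(90)
  # pure noise: amplitude is a few noise SDs, far below snr_min = 10
  expect_true(is_negative_reaction(rnorm(40)))

  # noise-free sigmoid: zero baseline noise but positive amplitude
  sig <- simulate_curve("sigmoid", noise_sd = 0)$curve
  expect_false(is_negative_reaction(sig$fluorescence))

  # all-zero curve is degenerate-negative
  expect_true(is_negative_reaction(rep(0, 40)))

  # noisy but strong amplification passes the gate
  sig <- simulate_curve("sigmoid", amplitude = 2, noise_sd = 0.01, seed = 2)$curve
  expect_false(is_negative_reaction(sig$fluorescence))

  expect_error(is_negative_reaction(rnorm(5)), "at least 10")
})

test_that("hookreg encodes failure modes in status, never errors", {
  # monotone sigmoid peaking at the last cycle: no tail to regress
  sig <- simulate_curve("no_plateau", noise_sd = 0)$curve
  call <- hookreg(sig)
  expect_false(call$hook)
  expect_equal(call$status, "insufficient_tail")

  # negative reaction
  set.seed(14)
  neg <- amp_curves(tibble::tibble(
    well_id = "N01", cycle = 1:40, fluorescence = rnorm(40, 5, 0.1)
  ))
  call <- hookreg(neg)
  expect_false(call$hook)
  expect_equal(call$status, "negative_reaction")

  # status != ok always implies hook == FALSE on a mixed plate
  plate <- simulate_plate(10, noise_sd = 0.01, seed = 3)
  calls <- hookreg(plate$curves)
  expect_true(all(!calls$hook[calls$status != "ok"]))
  expect_true(all(calls$status[calls$hook] == "ok"))
})

test_that("hookreg recovers a known tail slope on a plateau-decline curve", {
  # plateau at 1.0 from cycle 30, then -0.01/cycle decline to cycle 45
  curve <- piecewise_hook_curve(
    n_cycles = 45, peak_cycle = 30, decline = 0.01, noise_sd = 1e-4, seed = 8
  )
  call <- hookreg(curve)
  expect_true(call$hook)
  expect_equal(call$status, "ok")
  expect_gt(call$slope, -0.012)
  expect_lt(call$slope, -0.008)

  # the reported slope matches an independent fit of the same tail window
  y <- curve$fluorescence
  yn <- (y - min(y)) / unname(quantile(y - min(y), 0.99))
  x0 <- call$hook_start_cycle
  idx <- which(curve$cycle >= x0)
  orc <- ols_oracle(curve$cycle[idx], yn[idx])
  expect_equal(call$slope, orc$slope, tolerance = 1e-10)
  expect_equal(call$p_value, orc$p, tolerance = 1e-10)
  expect_equal(call$ci_low, orc$ci_low, tolerance = 1e-10)
})

test_that("hook decisions are invariant under positive affine transforms", {
  plate <- simulate_plate(8, noise_sd = 0.005, seed = 17) # 40 curves
  base <- hookreg(plate$curves)
  for (ab in list(c(3.7, 0), c(0.25, 12), c(1500, -4))) {
    tr <- plate$curves
    tr$fluorescence <- ab[1] * tr$fluorescence + ab[2]
    got <- hookreg(tr)
    expect_equal(got$hook, base$hook)
    expect_equal(got$status, base$status)
  }
})

test_that("steeper negative tails never flip a detection off", {
  # fixed noise realization, increasing hook severity
  set.seed(55)
  noise <- rnorm(45, sd = 0.003)
  detected <- vapply(c(-0.006, -0.01, -0.02, -0.04), function(k) {
    sim <- simulate_curve("hook", amplitude = 2, drift = k, noise_sd = 0)
    cr <- sim$curve
    cr$fluorescence <- cr$fluorescence + noise
    hookreg(cr)$hook
  }, logical(1))
  expect_false(is.unsorted(detected)) # once TRUE, stays TRUE
  expect_true(detected[4])
})

test_that("flat plateaus stay below the nominal false-positive budget", {
  # zero-slope plateau after the maximum: the one-sided test at alpha
  # should fire rarely; allow small-sample inflation up to 4x alpha
  set.seed(77)
  alpha <- 0.0025
  n_sim <- 10000
  x <- 1:20
  fp <- 0
  for (i in seq_len(n_sim)) {
    y <- 1 + rnorm(20, sd = 0.005) # flat tail segment, normalized scale
    fit <- ols_line(x, y, alpha = alpha)
    sig <- (!is.na(fit$p_one_sided) && fit$p_one_sided < alpha) ||
      (!is.na(fit$ci_high) && fit$ci_high < 0 && fit$ci_low < 0)
    fp <- fp + sig
  }
  expect_lte(fp / n_sim, 4 * alpha)
})
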