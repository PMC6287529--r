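test_that("the l6 model matches its defining formula", {
  # midpoint identity: with f = 1 and k = 0, y(e) = (c + d) / 2
  expect_equal(l6_model(20, b = -8, c = 0, d = 1, e = 20, f = 1, k = 0), 0.5)
  expect_equal(l6_model(15, b = -3, c = 0.2, d = 1.8, e = 15, f = 1, k = 0), 1)

  # collapsed sigmoid (c = d = 0): pure linear term
  expect_equal(l6_model(10, b = -8, c = 0, d = 0, e = 20, f = 1, k = 0.01), 0.1)

  # direct transcription oracle over a grid of parameters and cycles
  set.seed(61)
  for (i in 1:100) {
    pars <- list(
      b = runif(1, -15, -3), c = runif(1, 0, 0.3), d = runif(1, 0.5, 3),
      e = runif(1, 10, 35), f = runif(1, 0.3, 2.5), k = runif(1, -0.02, 0.02)
    )
    x <- runif(1, 1, 45)
    expect_equal(
      do.call(l6_model, c(list(x = x), pars)),
      do.call(l6_direct, c(list(x = x), pars)),
      tolerance = 1e-12
    )
  }
  expect_equal(
    l6_model(35, b = -10, c = 0.1, d = 1, e = 22, f = 0.7, k = -0.004),
    l6_direct(35, b = -10, c = 0.1, d = 1, e = 22, f = 0.7, k = -0.004),
    tolerance = 1e-12
  )

  expect_error(l6_model(0, b = -8, c = 0, d = 1, e = 20, f = 1, k = 0), "positive")
  expect_error(l6_model(5, b = -8, c = 0, d = 1, e = -1, f = 1, k = 0), "`e`")
  expect_error(l6_model(5, b = -8, c = 0, d = 1, e = 20, f = 0, k = 0), "`f`")
})

test_that("noise-free self-generated curves are recovered exactly", {
  truth <- list(b = -9, c = 0.15, d = 1.6, e = 23, f = 1.2, k = -0.006)
  x <- 1:45
  curve <- amp_curves(tibble::tibble(
    well_id = "T01", cycle = as.numeric(x),
    fluorescence = do.call(l6_model, c(list(x = x), truth))
  ))
  fit <- fit_l6(curve, normalize = FALSE)
  expect_true(fit$converged)
  for (p in names(truth)) {
    expect_equal(fit[[p]], truth[[p]], tolerance = 1e-4)
  }
  # exact-fit convention: point CI at the recovered drift
  expect_equal(fit$k_ci_low, fit$k)
  expect_equal(fit$k_ci_high, fit$k)

  # zero drift: the numerical zero is reported as exactly zero, CI holds 0
  truth$k <- 0
  curve$fluorescence <- do.call(l6_model, c(list(x = x), truth))
  fit <- fit_l6(curve, normalize = FALSE)
  expect_true(fit$converged)
  expect_identical(fit$k, 0)
  expect_true(fit$k_ci_low <= 0 && fit$k_ci_high >= 0)
})

test_that("drift is recovered within tolerance under noise", {
  set.seed(29)
  k_true <- -0.005
  for (i in 1:25) {
    sim <- simulate_curve("hook", amplitude = 1, drift = k_true, noise_sd = 1e-3)
    fit <- fit_l6(sim$curve, normalize = FALSE)
    expect_true(fit$converged)
    expect_lt(abs(fit$k - k_true), 0.002)
    expect_lt(fit$k_ci_high, 0) # CI excludes zero drift
  }
})

test_that("flat noise curves never yield a confident negative drift", {
  set.seed(41)
  spurious <- 0
  for (i in 1:100) {
    curve <- amp_curves(tibble::tibble(
      well_id = "F01", cycle = as.numeric(1:45),
      fluorescence = rnorm(45, mean = 0.5, sd = 0.05)
    ))
    fit <- fit_l6(curve, normalize = FALSE)
    if (fit$converged && fit$k_ci_high < 0) spurious <- spurious + 1
  }
  expect_equal(spurious, 0)
})

test_that("fit_l6 reports insufficient data and failures in status", {
  short <- amp_curves(tibble::tibble(
    well_id = "S01", cycle = as.numeric(1:10), fluorescence = as.numeric(1:10)
  ))
  fit <- fit_l6(short) # 5 points after trimming, fewer than 12
  expect_false(fit$converged)
  expect_equal(fit$status, "insufficient_data")

  flat <- amp_curves(tibble::tibble(
    well_id = "S02", cycle = as.numeric(1:30), fluorescence = rep(1, 30)
  ))
  fit <- fit_l6(flat)
  expect_false(fit$converged)
  expect_equal(fit$status, "fit_failed")
})

test_that("hookregnl calls hooks and encodes gate/fit failures", {
  # flat-plateau sigmoid: no hook
  sig <- simulate_curve("sigmoid", noise_sd = 0)$curve
  call <- hookregnl(sig)
  expect_false(call$hook)

  # pronounced simulated hook
  sim <- simulate_curve("hook", amplitude = 2, drift = -0.008, noise_sd = 1e-3, seed = 6)
  call <- hookregnl(sim$curve)
  expect_true(call$hook)
  expect_equal(call$status, "ok")
  expect_true(is.na(call$p_value)) # interval-based decision, no p-value

  # negative reaction gated out before fitting
  set.seed(19)
  neg <- amp_curves(tibble::tibble(
    well_id = "N01", cycle = as.numeric(1:40), fluorescence = rnorm(40, 3, 0.2)
  ))
  call <- hookregnl(neg)
  expect_false(call$hook)
  expect_equal(call$status, "negative_reaction")
})

test_that("hookregnl decisions are invariant under positive scaling", {
  plate <- simulate_plate(8, noise_sd = 0.005, seed = 23)
  base <- hookregnl(plate$curves)
  for (a in c(0.2, 5, 800)) {
    tr <- plate$curves
    tr$fluorescence <- a * tr$fluorescence
    got <- hookregnl(tr)
    expect_equal(got$hook, base$hook)
  }
})

test_that("tidy and glance summarize an l6 fit", {
  sim <- simulate_curve("hook", drift = -0.01, noise_sd = 1e-3, seed = 31)
  fit <- fit_l6(sim$curve)
  td <- tidy(fit)
  expect_equal(td$term, c("b", "c", "d", "e", "f", "k"))
  expect_equal(td$estimate[6], fit$k)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$k_ci_high, fit$k_ci_high)
})
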