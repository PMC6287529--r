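---
title: "Detecting hook effects in qPCR amplification curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hook effects in qPCR amplification curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hookdetect)
library(dplyr)
```

## The problem

A regular qPCR amplification curve rises through a ground (baseline) phase,
an exponential phase and a linear phase into a plateau where product no
longer accumulates. In some reactions the plateau instead *declines* cycle
after cycle — the hook effect. With hybridization probes the mechanism is
re-annealing of amplicon strands out-competing probe binding at high product
concentration; intercalating dyes and (in raw, non-baselined data) hydrolysis
probes show similar negative trends for other reasons. Whatever the
mechanism, a hooked plateau biases any quantification method that uses
plateau values, so such curves should be flagged during quality control and
either re-analyzed with plateau-independent methods or excluded.

`hookdetect` automates that flagging with two complementary detectors plus
their logical-OR combination.

## The linear detector: `hookreg()`

For each well, on raw (non-baselined) fluorescence:

1. **Negative-reaction gate.** The signal-to-noise ratio
   `(max(y) - min(y)) / sd(y[1:10])` must reach `snr_min` (default 10).
   Failed reactions have no plateau to interrogate; regressing their noise
   would produce meaningless calls. The gate and its default are this
   package's construction; both are exposed as parameters. A zero
   ground-phase standard deviation with positive amplitude counts as
   infinite SNR; an entirely flat trace is negative.
2. **Normalization.** `y' = (y - min y) / q99(y - min y)` with the
   linear-interpolation 99th percentile. This puts slopes on a common
   scale (the maximum lands just above 1); the decision itself is invariant
   to positive affine transforms of fluorescence.
3. **Locate the maximum** `x0 = argmax y'`, ties broken by the *earliest*
   cycle, which maximizes the tail available for regression.
4. **Tail length check.** At least `min_tail` (default 5) cycles must
   follow `x0`; a curve still rising at the end of the run has no
   interrogable tail and is reported `insufficient_tail` rather than
   forced through a two-point fit.
5. **Tail regression.** Ordinary least squares of `y'` on cycles
   `x0..xn` (the window includes `x0`). The slope `b1` gets a one-sided
   lower-tail t test (`df = m - 2`) and a symmetric `(1 - alpha)` CI.
6. **Decision.** Hook if `p < alpha` *or* both CI bounds are negative.
   The default `alpha = 0.0025` gives a 99.75% interval with bounds at the
   0.125% and 99.875% quantiles; a more permissive reading (`alpha =
   0.005`, 99.5% CI) is one flag away, and relaxing `alpha` can only add
   positives.

Zero-residual data (a perfect line) would make the t statistic 0/0; the
package defines that case as maximal evidence: `se = 0`, `p = 0` for a
negative slope and `1` otherwise, CI collapsed to the point estimate. A
numerically-zero slope on flat data is snapped to exactly zero first, so
its sign is never a rounding artefact. With only two tail points the slope
is exact but `se`, `p` and the CI are `NA`.

## The nonlinear detector: `hookregnl()`

A hook is a linear distortion of an otherwise sigmoidal curve, so the
second detector fits the six-parameter log-logistic model

$$y_i = c + k x_i + \frac{d - c}{\left(1 + \exp\!\big(b(\log x_i - \log e)\big)\right)^{f}}$$

with `c`/`d` the lower/upper asymptotes, `b` the sigmoidal slope, `e` the
inflection point (exactly, when `f = 1`), `f` the asymmetry factor and `k`
the linear drift. A negative `k` bends the plateau downward. After the
same negative-reaction gate, the first `trim` (default 5, extendable)
baseline cycles are removed — a sloping ground phase otherwise leaks into
`k` and causes false positives — and the curve is normalized as above.
The decision uses only the `(1 - alpha)` CI of `k`: hook if both bounds
are negative. No p-value is reported for this method; the interval is the
evidence.

Numerical choices, all of which matter in practice:

* **Optimizer.** Bounded Levenberg–Marquardt least squares
  (`minpack.lm::nlsLM`) with `f > 0` and `e` inside the observed cycle
  range; at most 1000 evaluations, cost tolerance 1e-8.
* **Starting values.** `c = min(y)`, `d = max(y)`, `e` at the steepest
  single-cycle gain, `f = 1`, `k = 0`, and `b` started at -10, -5 and
  -20. All three starts are run and the lowest-RSS fit kept: the
  six-parameter surface has genuine local minima, most visibly for
  truncated sigmoids whose inflection sits near the last cycle, where a
  single start can park `e` at its bound and manufacture a spuriously
  tight, negative CI for `k`.
* **Inference.** `se(k)` from the Jacobian-based covariance; CI via the t
  distribution with `m - 6` degrees of freedom.
* **Exact-fit convention.** When the residual sum of squares is
  numerically zero (below `eps^(2/3)` relative to the signal), the
  residual-based covariance carries no information and the optimizer's
  stopping error, not statistics, dominates the estimate of `k`. The
  package then reports `k` to numerical precision (|k| below 1e-8 on the
  normalized scale is reported as exactly 0) with a point CI — the
  analogue of the perfect-line convention above. Without this, a
  noise-free flat-plateau curve is a coin flip.
* **Failure handling.** Non-convergence, a singular covariance or fewer
  than 12 post-trim points (six parameters need residual degrees of
  freedom) map to `status = "fit_failed"` / `"insufficient_data"` with
  `hook = FALSE`; batch analysis of a plate never aborts on one bad well.

## The combination

`hook_calls(curves, method = "combined")` is the OR of the two detectors.
They fail in complementary ways: the linear detector needs a maximum at
least five cycles before the end of the run, so it misses slight drifts
whose maximum comes late; the nonlinear detector needs a fittable sigmoid
but sees a slight drift over the whole plateau. By set algebra the OR has
sensitivity at least the maximum, and specificity at most the minimum, of
the two — the package's tests assert exactly that on random call sets.

## Benchmarking

`evaluate_calls()` crosses calls with human ratings (`y`/`n` files read by
`read_labels()`) into confusion counts and sensitivity, specificity, false
positive/negative rates and accuracy; zero-denominator ratios are `NA`,
never a silent 0. Values are stored at full precision and rounded to two
decimals only for display (`format_performance()`). As an
internal-consistency anchor: counts (TP 19, TN 73, FP 2, FN 2) map to
sensitivity 0.90, specificity 0.97, accuracy 0.96, and
(TP 21, TN 73, FP 2, FN 0) to 1.00 / 0.97 / 0.98 at two decimals.

## What the simulator emulates — and what it does not

`simulate_curve()` draws `y_i = l6(x_i) + N(0, noise_sd^2)` over (default)
45 cycles; `simulate_plate()` builds balanced labelled plates over five
classes: regular sigmoids, negative reactions (baseline plus noise, zero
amplitude), no-plateau curves (midpoint forced beyond 92% of the run),
slight negative plateau trends and pronounced hooks. Randomized parameter
ranges: baseline `c` in [0, 0.2], amplitude `d - c` in [0.5, 3] RFU,
midpoint `e` in [15, 25] cycles, steepness `b` in [-15, -5], asymmetry `f`
in [0.5, 2]; drift `k` in [-0.01, -0.005] (slight) and [-0.03, -0.015]
(pronounced) normalized RFU per cycle; noise sd defaults to 0.005. These
ranges are this package's construction. Hook-class curves draw amplitudes
from the upper range [1.5, 3]: hook effects arise at high template
concentration, i.e. in strong-signal reactions, and a pronounced global
drift on a weak-amplitude curve would tilt the ground phase enough to trip
the SNR gate — a geometry real hooked curves do not show.

The simulator is deliberately simple: Gaussian, homoscedastic noise; a
single global linear drift rather than a plateau-only decline; no
per-cycle efficiency kinetics, no probe chemistry differences, no
instrument drift or spatial plate effects. Passing tests on simulated
plates therefore demonstrate that the algorithms recover the structures
they model, under noise levels typical of normalized instrument data —
not that they match human raters on any particular real data set. For
real-data validation, export a plate and ratings and run
`benchmark_plate()`; the acceptance test for the published 96-well
reference plate documents the expected counts and activates when that
plate is placed under `inst/extdata/`.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` use: 1000 random instances for
the OLS-versus-normal-equations comparison (agreement to 1e-10 relative);
500 replicates for drift recovery and CI coverage at `k = -0.005`,
noise sd 1e-3 (coverage at least 98% at the 99.75% level); 200 curves for
affine-invariance; a 500-curve noisy benchmark and a 25-curve noise-free
plate for classifier metrics; 100 pure-noise seeds for the
negative-reaction contract; and 10,000 simulated flat plateaus bounding
the one-sided test's false-positive rate at no more than four times
`alpha`. These sizes make the whole suite run in about a minute on a
single core while keeping Monte-Carlo error well below the asserted
margins.

## Known limitations

* The negative-reaction gate assumes the first ten cycles are ground
  phase; very early amplification (midpoint before cycle ~10) inflates the
  noise estimate and can gate out a true amplification curve.
* The linear detector cannot, by design, call curves whose maximum falls
  in the last `min_tail` cycles; that is what the nonlinear detector and
  the OR combination are for.
* The l6 drift term is global: a strongly sloping baseline that survives
  trimming biases `k`. Increase `trim` for long baselines.
* No Cq values, amplification efficiencies or melting-curve analysis are
  computed; this package is a quality-control gate upstream of
  quantification.
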