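# Drift sweeps, hysteresis detection, limit cycles, phase durations, and
# regime classification mechanics.

test_that("zero-width sweep reduces to the steady state", {
  net <- nominal_network()
  sw <- slow_drift_sweep(net, sweep_config("AMPK", c(3e4, 3e4), "up"),
                         fixed_rapa = 0)
  expect_equal(nrow(sw), 1)
  ob <- observables(net, unstressed_ss()$state)
  expect_equal(sw$frac_AMBRA1_P, ob$frac_AMBRA1_P, tolerance = 1e-6)
})

test_that("halving the drift rate leaves branch values within 1%", {
  nf <- no_feedback_network()
  cfg1 <- sweep_config("AMPK", c(0, 1e5), "up")
  sw1 <- slow_drift_sweep(nf, cfg1, fixed_rapa = 0)
  k_half <- attr(sw1, "k_eps") / 2
  sw2 <- slow_drift_sweep(nf, sweep_config("AMPK", c(0, 1e5), "up",
                                           k_eps = k_half), fixed_rapa = 0)
  grid <- seq(2e3, 9.8e4, length.out = 60)
  f1 <- stats::approx(sw1$input, sw1$frac_AMBRA1_P, grid, ties = mean)$y
  f2 <- stats::approx(sw2$input, sw2$frac_AMBRA1_P, grid, ties = mean)$y
  # compare away from the jump, where branches are smooth
  smooth <- abs(f1 - f2) < 0.5
  expect_gt(mean(smooth), 0.9)
  expect_lt(max(abs(f1 - f2)[smooth]), 0.01)
})

test_that("square-wave observable gives exact phase durations", {
  period <- 1000; duty <- 0.3
  time <- seq(0, 10 * period, by = 1)
  frac <- ifelse((time %% period) < duty * period, 0.9, 0.1)
  ph <- measure_phase_durations(data.frame(time = time,
                                           frac_AMBRA1_P = frac))
  expect_equal(ph$period, period, tolerance = 1e-2)
  expect_equal(ph$autophagy, duty * period, tolerance = 1e-2)
  expect_equal(ph$autophagy + ph$translation, ph$period, tolerance = 1e-9)
})

test_that("phase measurement rejects non-oscillating input", {
  flat <- data.frame(time = 0:100, frac_AMBRA1_P = rep(0.2, 101))
  expect_error(measure_phase_durations(flat), "never crosses")
  lc <- list(oscillating = FALSE)
  expect_error(measure_phase_durations(lc), "not oscillating")
})

test_that("limit-cycle detection separates the published fixed-input regimes", {
  net <- nominal_network()
  osc <- detect_limit_cycle(net, y0 = stressed_state(ampk = 9e4))
  expect_true(osc$oscillating)
  expect_gt(osc$env_max - osc$env_min, 0.5)
  expect_gt(osc$period, 0)
  steady <- detect_limit_cycle(net, y0 = stressed_state(ampk = 1.5e5))
  expect_false(steady$oscillating)
  expect_gt(steady$steady_obs$frac_AMBRA1_P, 0.5)
})

test_that("degenerate all-zero-rate model is classified as not oscillating", {
  net <- nominal_network()
  rate_names <- c(sensitivity_parameters(), "p9")
  net0 <- network_with_params(
    net, stats::setNames(as.list(rep(0, length(rate_names))), rate_names))
  lc <- detect_limit_cycle(net0, y0 = net0$init, window = 3600, n_out = 50)
  expect_false(lc$oscillating)
})

test_that("uniform inputs give a uniform regime map", {
  net <- nominal_network()
  d <- two_param_diagram(net, "AMPK", c(2.8e4, 3.2e4), "rapa", c(0, 0),
                         mode = "oscillation", nbins = 2)
  expect_equal(nrow(d), 4)
  expect_true(all(d$regime == "monostable-translation"))
})

test_that("regime maps are invariant to row traversal order", {
  nf <- no_feedback_network()
  d1 <- two_param_diagram(nf, "AMPK", c(0, 1e5), "p9", c(0, 1e-6),
                          mode = "bistability", nbins = 10)
  d2 <- two_param_diagram(nf, "AMPK", c(0, 1e5), "p9", c(1e-6, 0),
                          mode = "bistability", nbins = 10)
  key <- function(d) d[order(d$y, d$x_mid), c("x_mid", "y", "regime")]
  expect_equal(key(d1), key(d2), ignore_attr = TRUE)
})
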