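# Response-pattern classification and robustness-range mechanics.

test_that("nominal model is canonical on both stress scans", {
  net <- nominal_network()
  ra <- classify_response(net, "AMPK")
  rr <- classify_response(net, "rapa")
  expect_true(ra$canonical)
  expect_true(rr$canonical)
  expect_equal(ra$regimes, c("translation", "oscillatory", "autophagy"))
  # the oscillation window brackets the known oscillatory stress points
  expect_gt(9e4, ra$window[1]); expect_lt(9e4, ra$window[2])
  expect_gt(6e3, rr$window[1]); expect_lt(6e3, rr$window[2])
})

test_that("degenerate one-point multiplier grid returns the nominal point", {
  net <- nominal_network()
  r <- robustness_range(net, "p4", multipliers = 1)
  expect_equal(r$lo, 1)
  expect_equal(r$hi, 1)
  expect_true(r$fully_robust)
})

test_that("multiplier grid must contain the nominal value", {
  net <- nominal_network()
  expect_error(robustness_range(net, "p4", multipliers = c(0.5, 2)),
               "nominal multiplier")
})

test_that("robustness intervals are contiguous and contain the nominal", {
  net <- nominal_network()
  cache <- new.env()
  r <- robustness_range(net, "u2", multipliers = 10^(c(-2, -1, 0, 1, 2) / 4),
                        cache = cache)
  expect_true(r$lo <= 1 && r$hi >= 1)
  evaluated <- !is.na(r$ok)
  inside <- r$ok[evaluated]
  # evaluated points form TRUE run bounded by at most one FALSE on each side
  expect_true(all(diff(which(inside)) == 1))
})

test_that("a stub-canonical classifier marks every parameter fully robust", {
  # plumbing check: with the scans forced canonical, the bar spans the grid
  net <- nominal_network()
  stub_cache <- new.env()
  mult <- 10^(c(-8, 0, 8) / 4)
  for (p in sensitivity_parameters())
    for (m in mult)
      stub_cache[[if (m == 1) "nominal" else
        paste(p, format(m, digits = 12), sep = "|")]] <- TRUE
  rows <- lapply(sensitivity_parameters(), function(p)
    robustness_range(net, p, multipliers = mult, cache = stub_cache))
  expect_length(rows, 22)
  expect_true(all(vapply(rows, function(r) r$fully_robust, TRUE)))
})
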