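# Mass-action RHS, integration, observables, conservation, steady states,
# and input resets.

test_that("single-reaction RHS follows the mass-action definition", {
  t <- toy_models()$dimer
  net <- expand_network(t$model)
  rhs <- build_rhs(net)
  iA <- match("A(b)", net$species)
  iB <- match("B(a)", net$species)
  iAB <- setdiff(seq_along(net$species), c(iA, iB))
  x <- numeric(3); x[iA] <- 50; x[iB] <- 20
  dx <- rhs$derivative(x)
  kon <- t$model$params$kon
  expect_equal(dx[iAB], kon * 50 * 20)
  expect_equal(dx[iA], -kon * 50 * 20)
})

test_that("compiled RHS and Jacobian agree with a direct reaction-table oracle", {
  set.seed(7)
  for (nm in c("scaffold", "phosphoforms")) {
    net <- expand_network(toy_models()[[nm]]$model)
    rhs <- build_rhs(net)
    for (rep in 1:5) {
      x <- stats::runif(length(net$species), 0, 200)
      expect_equal(rhs$derivative(x), oracle_derivative(net, x),
                   tolerance = 1e-12, info = nm)
    }
    # Jacobian vs central finite differences of the oracle
    x <- stats::runif(length(net$species), 10, 100)
    J <- rhs$jacobian(x)
    h <- 1e-4
    for (j in seq_along(x)) {
      xp <- x; xm <- x
      xp[j] <- x[j] + h; xm[j] <- x[j] - h
      expect_equal(J[, j],
                   (oracle_derivative(net, xp) - oracle_derivative(net, xm)) / (2 * h),
                   tolerance = 1e-6, info = nm)
    }
  }
})

test_that("nominal-network RHS matches the oracle at random states", {
  net <- nominal_network()
  rhs <- build_rhs(net)
  set.seed(11)
  for (rep in 1:3) {
    x <- stats::runif(length(net$species), 0, 1e4)
    expect_equal(rhs$derivative(x), oracle_derivative(net, x),
                 tolerance = 1e-10)
  }
})

test_that("zero state gives zero derivative", {
  net <- nominal_network()
  expect_true(all(build_rhs(net)$derivative(numeric(length(net$species))) == 0))
})

test_that("molecule-type totals are conserved along trajectories", {
  net <- nominal_network()
  y0 <- stressed_state(ampk = 9e4)
  tr <- simulate_network(net, duration = 8 * 3600, y0 = y0, n_out = 200)
  tot <- mtorswitch:::type_totals(net, tr$states)
  for (tp in colnames(tot)) {
    if (tot[1, tp] == 0) next
    expect_lt(max(abs(tot[, tp] / tot[1, tp] - 1)), 1e-3, label = tp)
  }
  expect_equal(unname(tot[, "MTOR"]), rep(2e4, nrow(tot)), tolerance = 1e-3)
})

test_that("observable fractions stay within [0, 1]", {
  net <- nominal_network()
  tr <- simulate_network(net, duration = 4 * 3600,
                         y0 = stressed_state(ampk = 9e4), n_out = 100)
  expect_true(all(as.matrix(tr$obs) >= -1e-9 & as.matrix(tr$obs) <= 1 + 1e-9))
})

test_that("unstressed steady state is a translation state", {
  ss <- unstressed_ss()
  expect_true(ss$converged)
  ob <- observables(nominal_network(), ss$state)
  expect_gt(ob$frac_EIF4EBP1_P, 0.5)
  expect_lt(ob$frac_AMBRA1_P, 0.5)
  # the translation state carries inhibitory ULK1 S758 phosphorylation
  expect_gt(ob$frac_ULK1_S758_P, 0.5)
  expect_lt(ob$frac_RPTOR_S792_P, 0.5)
})

test_that("no-feedback model has two coexisting states at baseline inputs", {
  nf <- no_feedback_network()
  a <- find_steady_state(nf, y0 = nf$init)
  expect_true(a$converged)
  # prepare the other basin: drive to autophagy at high AMPK*, then step back
  high <- find_steady_state(nf, y0 = set_inputs(nf, nf$init, ampk_star = 1.5e5))
  b <- find_steady_state(nf, y0 = set_inputs(nf, high$state, ampk_star = 3e4))
  expect_true(b$converged)
  oa <- observables(nf, a$state)
  ob <- observables(nf, b$state)
  expect_lt(oa$frac_AMBRA1_P, 0.5); expect_gt(oa$frac_EIF4EBP1_P, 0.5)
  expect_gt(ob$frac_AMBRA1_P, 0.5); expect_lt(ob$frac_EIF4EBP1_P, 0.5)
})

test_that("all-zero rate constants leave the initial state fixed", {
  net <- nominal_network()
  rate_names <- c(sensitivity_parameters(), "p9")
  zeros <- stats::setNames(as.list(rep(0, length(rate_names))), rate_names)
  net0 <- network_with_params(net, zeros)
  ss <- find_steady_state(net0, y0 = net0$init)
  expect_true(ss$converged)
  expect_equal(ss$state, net0$init)
})

test_that("halving solver tolerances barely changes the endpoint", {
  net <- nominal_network()
  y0 <- stressed_state(ampk = 1.5e5)
  t1 <- simulate_network(net, duration = 6 * 3600, y0 = y0, n_out = 50)
  t2 <- simulate_network(net, duration = 6 * 3600, y0 = y0, n_out = 50,
                         rtol = 5e-9, atol = 5e-7)
  expect_lt(abs(tail(t1$obs$frac_AMBRA1_P, 1) - tail(t2$obs$frac_AMBRA1_P, 1)),
            1e-4)
})

test_that("input resets add or remove only free monomer copies", {
  net <- nominal_network()
  y <- set_inputs(net, unstressed_ss()$state, ampk_star = 9e4,
                  rapamycin_star = 500)
  tot <- mtorswitch:::type_totals(net, y)
  expect_equal(unname(tot[, "AMPK"]), 9e4)
  expect_equal(unname(tot[, "rapa"]), 500)
  expect_error(set_inputs(net, y, ampk_star = 10),
               "cannot reduce")
})
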