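# Mass-action ODE simulation of an expanded reaction network: RHS assembly,
# stiff integration, observables (phosphorylation fractions), steady states,
# and input (stress) application.

# precompute the structural integration arrays (reactant indices and net
# stoichiometry triplets); cached per network via its reference-semantics
# cache environment, since the structure does not depend on rate values
ode_arrays <- function(network) {
  cache <- network$cache
  if (!is.null(cache) && !is.null(cache$arrays)) return(cache$arrays)
  rr <- network$reactions
  nr <- nrow(rr)
  ns <- length(network$species)
  sp <- c(rr$r1, rr$r2, rr$p1, rr$p2)
  rx <- rep.int(seq_len(nr), 4L)
  co <- rep(c(-1, -1, 1, 1), each = nr)
  ok <- !is.na(sp)
  agg <- rowsum(co[ok], paste(sp[ok], rx[ok]))
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  ksp <- as.integer(vapply(parts, `[`, "", 1L))
  krx <- as.integer(vapply(parts, `[`, "", 2L))
  keep <- agg[, 1] != 0
  a <- list(r1 = ifelse(is.na(rr$r1), 0L, rr$r1),
            r2 = ifelse(is.na(rr$r2), 0L, rr$r2),
            s_sp = ksp[keep], s_rx = krx[keep], s_co = agg[keep, 1],
            nspecies = ns)
  if (!is.null(cache)) cache$arrays <- a
  a
}

#' Build the mass-action rate function of a network
#'
#' For each reaction the flux is rate value x product of reactant amounts
#' (squared when a reactant enters twice); the derivative of each species is
#' the stoichiometry-weighted sum of fluxes.
#'
#' @param network A `reaction_network`.
#' @return A list with `derivative(x)` (and `jacobian(x)`), plus
#'   deSolve-compatible `func` and `jacfunc`.
#' @export
build_rhs <- function(network) {
  a <- ode_arrays(network)
  a$k <- network$reactions$rate
  derivative <- function(x, k = a$k)
    rn_rhs_cpp(x, k, a$r1, a$r2, a$s_sp, a$s_rx, a$s_co, a$nspecies)
  jacobian <- function(x, k = a$k)
    rn_jac_cpp(x, k, a$r1, a$r2, a$s_sp, a$s_rx, a$s_co, a$nspecies)
  list(
    derivative = derivative,
    jacobian = jacobian,
    func = function(t, y, parms) list(derivative(y)),
    jacfunc = function(t, y, parms) jacobian(y),
    arrays = a)
}

# observable definitions: numerator site counts and denominator molecule type
observable_defs <- function() {
  list(
    frac_AMBRA1_P   = list(type = "AMBRA1",   site = "S/T",   num = list(c("ST", "P", 1))),
    frac_EIF4EBP1_P = list(type = "EIF4EBP1", site = "S65/T70", num = list(c("S65_T70", "P", 1))),
    frac_ULK1_S317_P = list(type = "ULK1", site = "S317", num = list(c("S317", "P", 1))),
    frac_ULK1_S758_P = list(type = "ULK1", site = "S758", num = list(c("S758", "P", 1))),
    frac_ULK1_S778_P = list(type = "ULK1", site = "S778", num = list(c("S778", "P", 1))),
    frac_RPTOR_S792_P = list(type = "RPTOR", site = "S792", num = list(c("S792", "P", 1))),
    frac_RPTOR_S855_S859 = list(type = "RPTOR", site = "S855/S859",
                                num = list(c("S855_S859", "P", 0.5),
                                           c("S855_S859", "PP", 1)))
  )
}

# numerator weight matrix (n_obs x n_species) and denominator type rows
observable_matrices <- function(network) {
  cache <- network$cache
  if (!is.null(cache) && !is.null(cache$obs)) return(cache$obs)
  defs <- observable_defs()
  ns <- length(network$species)
  W <- matrix(0, nrow = length(defs), ncol = ns,
              dimnames = list(names(defs), NULL))
  for (o in seq_along(defs)) {
    d <- defs[[o]]
    for (s in seq_len(ns)) {
      g <- network$graphs[[s]]
      w <- 0
      for (term in d$num)
        w <- w + as.numeric(term[3]) *
          species_site_count(g, d$type, term[1], term[2])
      W[o, s] <- w
    }
  }
  M <- composition_matrix(network)
  denM <- matrix(0, nrow = length(defs), ncol = ns,
                 dimnames = list(names(defs), NULL))
  for (o in seq_along(defs)) {
    tp <- defs[[o]]$type
    if (tp %in% rownames(M)) denM[o, ] <- M[tp, ]
  }
  obs <- list(W = W, M = M, denM = denM)
  if (!is.null(cache)) cache$obs <- obs
  obs
}

#' Compute observables from species amounts
#'
#' Phosphorylation fractions tracked by the model: the AMBRA1-P fraction
#' (autophagy proxy), the EIF4EBP1-P fraction (translation proxy), and
#' per-site fractions for ULK1 (S317, S758, S778) and RPTOR (S792, lumped
#' S855/S859 occupancy).  Fractions are numerator copies over the current
#' total of the carrier protein, so they remain well defined under input
#' drift.
#'
#' @param network A `reaction_network`.
#' @param x A species amount vector, or a matrix with one state per row.
#' @return A data frame of observable fractions (one row per state).
#' @export
observables <- function(network, x) {
  ob <- observable_matrices(network)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  num <- x %*% t(ob$W)
  den <- x %*% t(ob$denM)
  frac <- num / ifelse(den > 0, den, NA_real_)
  colnames(frac) <- rownames(ob$W)
  as.data.frame(frac)
}

# totals of each molecule type for a state vector or trajectory matrix
type_totals <- function(network, x) {
  M <- composition_matrix(network)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  tot <- x %*% t(M)
  colnames(tot) <- rownames(M)
  tot
}

#' Integrate the network ODEs
#'
#' Stiff BDF integration (via deSolve, with the network's analytic Jacobian)
#' of the mass-action system, at relative tolerance `rtol` (default 1e-8).
#'
#' @param network A `reaction_network`.
#' @param duration Simulated time, seconds.
#' @param y0 Initial species amounts; default the network's seed amounts.
#' @param n_out Number of evenly spaced output points.
#' @param times Explicit output times (overrides `duration`/`n_out`).
#' @param rtol,atol Integration tolerances.
#' @param method deSolve method; `"vode"` (BDF, analytic Jacobian) by default.
#' @param ramp Optional linear ramp on one rate parameter (used for
#'   rate-constant drift sweeps): a list with reaction indices `idx`, their
#'   base multipliers `base`, endpoint parameter values `p0`, `p1`, and ramp
#'   duration `T` (seconds).
#' @return A `trajectory`: list with `time`, `states` (time x species), and
#'   `obs` (data frame of observables per output time).
#' @export
simulate_network <- function(network, duration, y0 = NULL, n_out = 1000,
                             times = NULL, rtol = 1e-8, atol = 1e-6,
                             method = "vode", ramp = NULL) {
  if (is.null(y0)) y0 <- network$init
  if (is.null(times)) times <- seq(0, duration, length.out = n_out)
  a <- ode_arrays(network)
  rn_set_system(network$reactions$rate, a$r1, a$r2, a$s_sp, a$s_rx, a$s_co,
                a$nspecies)
  if (!is.null(ramp))
    rn_set_ramp(ramp$idx, ramp$base, ramp$p0, ramp$p1, ramp$T)
  sol <- deSolve::ode(y = y0, times = times, func = "rn_derivs",
                      jacfunc = "rn_jacobian", jactype = "fullusr",
                      dllname = "mtorswitch", initfunc = NULL, parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed at t = ", max(sol[, 1]), " s")
  states <- unname(sol[, -1, drop = FALSE])
  structure(list(time = sol[, 1], states = states,
                 obs = observables(network, states)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d time points over %g s; final frac_AMBRA1_P = %.3f, frac_EIF4EBP1_P = %.3f\n",
              length(x$time), max(x$time),
              x$obs$frac_AMBRA1_P[length(x$time)],
              x$obs$frac_EIF4EBP1_P[length(x$time)]))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  cbind(data.frame(time = x$time), x$obs)
}

#' Relax the network to a steady state
#'
#' Integrates with geometrically growing time chunks until the scaled
#' derivative `max |dx/dt| / max(1, x)` falls below `tol`, or the time cap is
#' reached.
#'
#' @param network A `reaction_network`.
#' @param y0 Initial amounts (default: seed amounts).
#' @param tol Convergence tolerance on the scaled derivative.
#' @param t_cap Maximum total integration time, seconds.
#' @return List with `state`, `converged`, `t_elapsed`.
#' @export
find_steady_state <- function(network, y0 = NULL, tol = 1e-10, t_cap = 1e7) {
  if (is.null(y0)) y0 <- network$init
  rhs <- build_rhs(network)
  scaled <- function(y) max(abs(rhs$derivative(y)) / pmax(1, abs(y)))
  y <- y0
  t_el <- 0
  dt <- 1000
  while (t_el < t_cap) {
    if (scaled(y) < tol)
      return(list(state = y, converged = TRUE, t_elapsed = t_el))
    tr <- simulate_network(network, duration = dt, y0 = y, n_out = 3)
    y <- tr$states[nrow(tr$states), ]
    t_el <- t_el + dt
    dt <- min(dt * 4, t_cap - t_el + 1)
  }
  list(state = y, converged = scaled(y) < tol, t_elapsed = t_el)
}

#' Reset input totals in a state vector
#'
#' Applies a step stress: the totals of AMPK* and/or rapamycin* are reset by
#' adding (or removing) copies of the corresponding unmodified monomer,
#' leaving all other species untouched.  A decrease larger than the free
#' monomer pool is an error.
#'
#' @param network A `reaction_network`.
#' @param state Species amount vector.
#' @param ampk_star,rapamycin_star Target totals (copies/cell); `NULL` leaves
#'   an input unchanged.
#' @return The adjusted state vector.
#' @export
set_inputs <- function(network, state, ampk_star = NULL, rapamycin_star = NULL) {
  tot <- type_totals(network, state)
  adjust <- function(state, type, target) {
    idx <- monomer_index(network, type)
    delta <- target - tot[1, type]
    if (state[idx] + delta < -1e-9 * max(1, target))
      stop("cannot reduce ", type, " below its bound/modified pool")
    state[idx] <- max(0, state[idx] + delta)
    state
  }
  if (!is.null(ampk_star)) state <- adjust(state, "AMPK", ampk_star)
  if (!is.null(rapamycin_star)) state <- adjust(state, "rapa", rapamycin_star)
  state
}

#' Unstressed steady state
#'
#' The reference state used as the starting point of stress simulations:
#' steady state at the model's baseline inputs (nominally AMPK* = 30,000
#' copies/cell and no rapamycin*).
#'
#' @param network A `reaction_network`.
#' @inheritParams find_steady_state
#' @return List with `state`, `converged`, `t_elapsed`.
#' @export
unstressed_state <- function(network, tol = 1e-10, t_cap = 1e7) {
  find_steady_state(network, y0 = network$init, tol = tol, t_cap = t_cap)
}

#' Replace rate-constant values without re-expanding the network
#'
#' Rule application is structural, so the species and reactions of the
#' expanded network do not depend on rate values; variants that only change
#' rate constants (e.g. the no-feedback variant, `p6 = 0`, or sensitivity
#' multipliers) can reuse one expansion.
#'
#' @param network A `reaction_network`.
#' @param overrides Named list of parameter values.
#' @return The network with updated parameters and reaction rates.
#' @export
network_with_params <- function(network, overrides) {
  params <- network$model$params
  for (nm in names(overrides)) {
    if (!nm %in% names(params)) stop("unknown parameter: ", nm)
    params[[nm]] <- overrides[[nm]]
  }
  network$model$params <- params
  rr <- network$reactions
  network$reactions$rate <- rr$stat_factor * rr$mult *
    unlist(params[rr$rate_ref], use.names = FALSE)
  network
}
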