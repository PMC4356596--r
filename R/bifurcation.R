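# Numerical bifurcation protocol: slow-drift sweeps of an input (or a rate
# constant), detection of bistability windows via up/down-sweep hysteresis,
# limit-cycle detection at fixed inputs, oscillation period and phase
# durations, and two-parameter regime diagrams.
#
# A sweep augments the network with a zeroth-order source (up) or first-order
# sink (down) on the drifted quantity, so that all other processes track a
# slowly moving pseudo-steady state; the system then traces stable branches
# and limit-cycle envelopes as the drifted quantity crosses bifurcation
# points.

.input_types <- c(AMPK = "AMPK", rapa = "rapa", ampk_star = "AMPK",
                  rapamycin_star = "rapa")

#' Sweep configuration
#'
#' @param param Drifted quantity: `"AMPK"` or `"rapa"` (input copy numbers),
#'   or the name of a rate constant (drifted by a linear ramp).
#' @param range Sweep range `c(low, high)` (copies/cell, or the rate
#'   constant's units).
#' @param direction `"up"` or `"down"`.
#' @param k_eps Drift rate (copies/cell/s for inputs).  Default: the range is
#'   traversed in 5000 characteristic response times (5000/u0 seconds), tying
#'   the drift to the system's slowest routine dephosphorylation step.
#' @param n_out Number of recorded points along the sweep.
#' @return A `sweep_config`.
#' @export
sweep_config <- function(param, range, direction = c("up", "down"),
                         k_eps = NULL, n_out = 2000) {
  direction <- match.arg(direction)
  stopifnot(length(range) == 2L, range[1] <= range[2], range[1] >= 0)
  structure(list(param = param, range = range, direction = direction,
                 k_eps = k_eps, n_out = n_out), class = "sweep_config")
}

# append drift reactions for an input species: a zeroth-order source of the
# monomer, or a first-order sink removing the molecule wherever it occurs
augment_drift_network <- function(network, type, mode = c("source", "sink"),
                                  rate) {
  mode <- match.arg(mode)
  rr <- network$reactions
  if (mode == "source") {
    idx <- monomer_index(network, type)
    add <- data.frame(rule = "drift", reverse = FALSE,
                      r1 = NA_integer_, r2 = NA_integer_,
                      p1 = idx, p2 = NA_integer_, rate_ref = "k_eps",
                      stat_factor = 1, mult = 1L, rate = rate,
                      stringsAsFactors = FALSE)
  } else {
    M <- composition_matrix(network)
    carriers <- which(M[type, ] > 0)
    rows <- lapply(carriers, function(s) {
      g <- network$graphs[[s]]
      keep <- vapply(g$mols, function(m) m$type != type, TRUE)
      p1 <- NA_integer_
      if (any(keep)) {
        drop_idx <- which(!keep)
        bonds <- Filter(function(b) !(b$m1 %in% drop_idx || b$m2 %in% drop_idx),
                        g$bonds)
        remap <- cumsum(keep)
        bonds <- lapply(bonds, function(b)
          list(m1 = remap[b$m1], s1 = b$s1, m2 = remap[b$m2], s2 = b$s2))
        rest <- new_species(g$mols[keep], bonds)
        comps <- split_components(rest)
        if (length(comps) != 1L)
          stop("drift sink: removal split species into several components")
        lab <- canonical_label(comps[[1]])
        p1 <- match(lab, network$species)
        if (is.na(p1)) stop("drift sink: product species not in network")
      }
      data.frame(rule = "drift", reverse = FALSE, r1 = s, r2 = NA_integer_,
                 p1 = p1, p2 = NA_integer_, rate_ref = "k_eps",
                 stat_factor = 1, mult = M[type, s],
                 rate = rate * M[type, s], stringsAsFactors = FALSE)
    })
    add <- do.call(rbind, rows)
  }
  network$reactions <- rbind(rr, add)
  network$cache <- new.env(parent = emptyenv())
  network
}

#' Slow-drift bifurcation sweep
#'
#' Integrates the network while the drifted quantity moves slowly across
#' `range`, recording the observables against the current value of the
#' drifted quantity.  Input sweeps start from the steady state at the range
#' end; the other input is held at `fixed_ampk`/`fixed_rapa`.  Down sweeps of
#' an input use a first-order sink and therefore approach the lower end
#' asymptotically; they are truncated at `max(low, high/1000)`.
#'
#' @param network An expanded `reaction_network`.
#' @param config A [sweep_config()].
#' @param fixed_ampk,fixed_rapa Level of the non-drifted input (defaults:
#'   the model's current input parameters).
#' @param y0 Optional starting state (default: steady state at the sweep's
#'   starting value).
#' @param rtol,atol Integration tolerances.
#' @return A `drift_sweep`: data frame with `time`, `input`, and observable
#'   columns; attributes `param`, `direction`, `k_eps`.
#' @export
slow_drift_sweep <- function(network, config, fixed_ampk = NULL,
                             fixed_rapa = NULL, y0 = NULL,
                             rtol = 1e-8, atol = 1e-6) {
  params <- network$model$params
  if (is.null(fixed_ampk)) fixed_ampk <- params$AMPK_star
  if (is.null(fixed_rapa)) fixed_rapa <- params$rapa_star
  # drift time scale: 5000 characteristic response times (1/u0); models
  # without a dephosphorylation time scale fall back to 100 s
  u0 <- if (!is.null(params$u0)) params$u0 else 1e-2
  lo <- config$range[1]; hi <- config$range[2]
  T_sweep <- 5000 / u0
  is_input <- config$param %in% names(.input_types)
  if (hi == lo) {
    # degenerate single-point sweep: plain relaxation to the attractor
    if (is_input) {
      type <- .input_types[[config$param]]
      inputs <- list(ampk_star = fixed_ampk, rapamycin_star = fixed_rapa)
      inputs[[if (type == "AMPK") "ampk_star" else "rapamycin_star"]] <- lo
      ssn <- network
      y0 <- set_inputs(network, network$init, inputs$ampk_star,
                       inputs$rapamycin_star)
      ss <- find_steady_state(ssn, y0 = y0)
      ob <- observables(network, ss$state)
      out <- cbind(data.frame(time = 0, input = lo), ob)
      return(structure(out, class = c("drift_sweep", "data.frame"),
                       param = config$param, direction = config$direction,
                       k_eps = 0))
    }
    stop("zero-width sweep of a rate constant")
  }

  if (is_input) {
    type <- .input_types[[config$param]]
    start_val <- if (config$direction == "up") lo else hi
    inputs <- list(ampk_star = fixed_ampk, rapamycin_star = fixed_rapa)
    inputs[[if (type == "AMPK") "ampk_star" else "rapamycin_star"]] <- start_val
    if (is.null(y0)) {
      y_init <- set_inputs(network, network$init, inputs$ampk_star,
                           inputs$rapamycin_star)
      y0 <- find_steady_state(network, y0 = y_init)$state
    }
    if (config$direction == "up") {
      k_eps <- if (is.null(config$k_eps)) (hi - lo) / T_sweep else config$k_eps
      net2 <- augment_drift_network(network, type, "source", k_eps)
      T_run <- (hi - lo) / k_eps
    } else {
      lo_eff <- max(lo, hi / 1000)
      k_eps <- if (is.null(config$k_eps)) log(hi / lo_eff) / T_sweep else config$k_eps
      net2 <- augment_drift_network(network, type, "sink", k_eps)
      T_run <- log(hi / lo_eff) / k_eps
    }
    tr <- simulate_network(net2, duration = T_run, y0 = y0,
                           n_out = config$n_out, rtol = rtol, atol = atol)
    input <- type_totals(network, tr$states)[, type]
  } else {
    if (!config$param %in% names(params))
      stop("unknown sweep parameter: ", config$param)
    p0 <- if (config$direction == "up") lo else hi
    p1 <- if (config$direction == "up") hi else lo
    if (is.null(y0)) {
      net0 <- network_with_params(network, stats::setNames(list(p0), config$param))
      y_init <- set_inputs(net0, net0$init, fixed_ampk, fixed_rapa)
      y0 <- find_steady_state(net0, y0 = y_init)$state
    }
    k_eps <- if (is.null(config$k_eps)) abs(hi - lo) / T_sweep else config$k_eps
    T_run <- abs(p1 - p0) / k_eps
    rr <- network$reactions
    idx <- which(rr$rate_ref == config$param)
    if (!length(idx)) stop("no reactions use parameter ", config$param)
    ramp <- list(idx = idx, base = rr$stat_factor[idx] * rr$mult[idx],
                 p0 = p0, p1 = p1, T = T_run)
    tr <- simulate_network(network, duration = T_run, y0 = y0,
                           n_out = config$n_out, rtol = rtol, atol = atol,
                           ramp = ramp)
    input <- p0 + (p1 - p0) * tr$time / T_run
  }
  out <- cbind(data.frame(time = tr$time, input = input), tr$obs)
  structure(out, class = c("drift_sweep", "data.frame"),
            param = config$param, direction = config$direction, k_eps = k_eps,
            states = tr$states)
}

# turning-point (zigzag) detection with a prominence threshold; returns
# committed alternating extrema
zigzag_extrema <- function(x, prominence) {
  n <- length(x)
  idx <- integer(0); type <- integer(0)
  mode <- 0L
  M <- x[1]; Mi <- 1L; m <- x[1]; mi <- 1L
  for (i in 2:n) {
    if (x[i] > M) { M <- x[i]; Mi <- i }
    if (x[i] < m) { m <- x[i]; mi <- i }
    if (mode != -1L && x[i] <= M - prominence) {
      idx <- c(idx, Mi); type <- c(type, 1L)
      mode <- -1L; m <- x[i]; mi <- i
    } else if (mode != 1L && x[i] >= m + prominence) {
      idx <- c(idx, mi); type <- c(type, -1L)
      mode <- 1L; M <- x[i]; Mi <- i
    }
  }
  list(idx = idx, type = type)
}

#' Oscillation window of a drift sweep
#'
#' Identifies the interval of the drifted quantity over which the swept
#' system shows sustained oscillations in `frac_AMBRA1_P`: at least
#' `min_peaks` prominent maxima whose span exceeds `min_width_frac` of the
#' sweep range.  The returned window spans all committed extrema, so single
#' jump transients (a switch with brief ringing) are not reported as
#' oscillation.
#'
#' @param sweep A `drift_sweep`.
#' @param observable Observable column used for detection.
#' @param prominence Amplitude threshold for a peak (fraction units).
#' @param min_peaks Minimum number of prominent maxima.
#' @param min_width_frac Minimum window width, as a fraction of the sweep
#'   range.
#' @return `c(low, high)` in input units, or `NULL` when there is no
#'   oscillatory window.
#' @export
oscillation_window <- function(sweep, observable = "frac_AMBRA1_P",
                               prominence = 0.01, min_peaks = 3,
                               min_width_frac = 0.02) {
  x <- sweep[[observable]]
  if (anyNA(x)) return(NULL)
  z <- zigzag_extrema(x, prominence)
  if (length(z$idx) > 0L) {
    # the first committed extremum is the endpoint of the starting branch's
    # monotone drift, not an oscillation
    z$idx <- z$idx[-1]
    z$type <- z$type[-1]
  }
  peaks <- z$idx[z$type == 1L]
  if (length(peaks) < min_peaks) return(NULL)
  pk <- sort(sweep$input[peaks])
  w <- range(pk)
  if (diff(w) < min_width_frac * diff(range(sweep$input))) return(NULL)
  # pad by one typical inter-peak spacing: the onset lies about one drifted
  # period before the first recorded peak
  pad <- stats::median(diff(pk))
  c(max(min(sweep$input), w[1] - pad), min(max(sweep$input), w[2] + pad))
}

#' Detect bistability from an up/down sweep pair
#'
#' Interpolates both sweeps onto a common grid of the drifted quantity and
#' reports the contiguous intervals where the up- and down-sweep branches of
#' `frac_AMBRA1_P` differ by more than `threshold` (hysteresis).
#'
#' @param up,down `drift_sweep` objects over the same range, directions
#'   `"up"` and `"down"`.
#' @param threshold Branch separation defining bistability (default 0.2).
#' @param observable Observable column compared.
#' @param n_grid Comparison grid size.
#' @return Data frame of bistable intervals (`lo`, `hi`, `max_gap`); zero
#'   rows when monostable.
#' @export
detect_bistability <- function(up, down, threshold = 0.2,
                               observable = "frac_AMBRA1_P", n_grid = 200) {
  lo <- max(min(up$input), min(down$input))
  hi <- min(max(up$input), max(down$input))
  grid <- seq(lo, hi, length.out = n_grid)
  fu <- stats::approx(up$input, up[[observable]], xout = grid, ties = mean)$y
  fd <- stats::approx(down$input, down[[observable]], xout = grid, ties = mean)$y
  gap <- abs(fu - fd)
  bist <- !is.na(gap) & gap > threshold
  if (!any(bist))
    return(data.frame(lo = numeric(0), hi = numeric(0), max_gap = numeric(0)))
  r <- rle(bist)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(lo = grid[starts[keep]], hi = grid[ends[keep]],
             max_gap = vapply(keep, function(k)
               max(gap[starts[k]:ends[k]]), 1))
}

#' Detect a stable limit cycle at fixed inputs
#'
#' Starts from the unstressed steady state, applies the stress inputs, and
#' integrates successive windows (default 40 h), discarding the first half of
#' each, until two consecutive windows agree in oscillation amplitude (or
#' until the amplitude falls below `amp_threshold`, i.e. a steady state).
#' The period is the mean midline-crossing interval; for small-amplitude
#' cycles (< 0.05) it falls back to the autocorrelation peak.
#'
#' @param network A `reaction_network`.
#' @param ampk_star,rapamycin_star Stress input levels (copies/cell).
#' @param y0 Optional starting state (default: unstressed steady state with
#'   the stress applied).
#' @param window Window length, seconds.
#' @param amp_threshold Peak-to-trough amplitude of `frac_AMBRA1_P` above
#'   which the attractor is classified as oscillating.
#' @param max_windows Classification cap; `oscillating = NA` (undetermined)
#'   if amplitudes have not settled by then.
#' @param n_out Output points per window.
#' @return List with `oscillating` (TRUE/FALSE/NA), `env_min`, `env_max`,
#'   `period` (s), `steady_obs` (observables at the final state), and the
#'   final window `trajectory` (data frame `time`, observables).
#' @export
detect_limit_cycle <- function(network, ampk_star = NULL, rapamycin_star = NULL,
                               y0 = NULL, window = 40 * 3600,
                               amp_threshold = 0.01, max_windows = 8,
                               n_out = 1600) {
  if (is.null(y0)) {
    ss <- unstressed_state(network)
    y0 <- set_inputs(network, ss$state, ampk_star, rapamycin_star)
  }
  prev_amp <- NA_real_
  prev_mean <- NA_real_
  y <- y0
  for (w in seq_len(max_windows)) {
    tr <- simulate_network(network, duration = window, y0 = y, n_out = n_out)
    y <- tr$states[nrow(tr$states), ]
    sel <- tr$time >= window / 2
    a <- tr$obs$frac_AMBRA1_P[sel]
    amp <- max(a) - min(a)
    if (amp < amp_threshold) {
      # candidate steady state; accept when the window means have settled
      if (!is.na(prev_mean) && abs(mean(a) - prev_mean) < 1e-3) {
        return(list(oscillating = FALSE, env_min = min(a), env_max = max(a),
                    period = NA_real_,
                    steady_obs = observables(network, y),
                    trajectory = cbind(data.frame(time = tr$time), tr$obs),
                    windows_used = w))
      }
    } else if (!is.na(prev_amp) && abs(amp - prev_amp) < 0.05 * amp) {
      per <- estimate_period(tr$time[sel], a)
      return(list(oscillating = TRUE, env_min = min(a), env_max = max(a),
                  period = per,
                  steady_obs = observables(network, y),
                  trajectory = cbind(data.frame(time = tr$time), tr$obs),
                  windows_used = w))
    }
    prev_amp <- if (amp >= amp_threshold) amp else NA_real_
    prev_mean <- mean(a)
  }
  list(oscillating = NA, env_min = NA_real_, env_max = NA_real_,
       period = NA_real_, steady_obs = observables(network, y),
       trajectory = NULL, windows_used = max_windows)
}

# period from midline crossings; autocorrelation fallback for small
# amplitudes where threshold crossing is unreliable
estimate_period <- function(time, x, small_amp = 0.05) {
  amp <- max(x) - min(x)
  mid <- (max(x) + min(x)) / 2
  above <- x > mid
  ups <- which(diff(above) == 1L)
  if (amp >= small_amp && length(ups) >= 2L) {
    # linear interpolation of crossing times
    tc <- time[ups] + (mid - x[ups]) / (x[ups + 1L] - x[ups]) *
      (time[ups + 1L] - time[ups])
    return(mean(diff(tc)))
  }
  ac <- stats::acf(x - mean(x), lag.max = length(x) - 2L, plot = FALSE)$acf[, 1, 1]
  # first local maximum after the initial decline
  d <- diff(ac)
  cand <- which(d[-1] < 0 & d[-length(d)] > 0) + 1L
  if (!length(cand)) return(NA_real_)
  (cand[1] - 1L) * mean(diff(time))
}

#' Durations of the autophagy and translation phases of an oscillation
#'
#' The autophagy phase is the part of each period with more than half of
#' AMBRA1 phosphorylated (`frac_AMBRA1_P > threshold`); the translation phase
#' is its complement, so the two durations sum to the period.
#'
#' @param x A limit-cycle result from [detect_limit_cycle()] (must be
#'   oscillating), or a data frame with columns `time` and `frac_AMBRA1_P`.
#' @param threshold Phase threshold on the AMBRA1-P fraction.
#' @return List with `autophagy`, `translation` (seconds), `period`, and the
#'   number of full periods measured.
#' @export
measure_phase_durations <- function(x, threshold = 0.5) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!isTRUE(x$oscillating))
      stop("measure_phase_durations: trajectory is not oscillating")
    x <- x$trajectory
    x <- x[x$time >= max(x$time) / 2, ]
  }
  time <- x$time
  v <- x$frac_AMBRA1_P
  above <- v > threshold
  if (all(above) || all(!above))
    stop("measure_phase_durations: series never crosses the phase threshold")
  cross <- function(i)  # interpolated crossing time in interval [i, i+1]
    time[i] + (threshold - v[i]) / (v[i + 1L] - v[i]) * (time[i + 1L] - time[i])
  ups <- which(diff(above) == 1L)
  downs <- which(diff(above) == -1L)
  if (length(ups) < 2L)
    stop("measure_phase_durations: need at least two full periods")
  t_up <- vapply(ups, cross, 1)
  t_dn <- vapply(downs, cross, 1)
  t0 <- t_up[1]; t1 <- t_up[length(t_up)]
  k <- length(t_up) - 1L
  period <- (t1 - t0) / k
  t_dn <- t_dn[t_dn > t0 & t_dn < t1]
  # time above threshold between t0 and t1: pair each up-crossing with the
  # following down-crossing
  t_above <- 0
  for (j in seq_len(length(t_up) - 1L)) {
    nxt <- t_dn[t_dn > t_up[j]]
    t_above <- t_above + (if (length(nxt)) min(nxt) else t1) - t_up[j]
  }
  autophagy <- t_above / k
  list(autophagy = autophagy, translation = period - autophagy,
       period = period, n_periods = k)
}

# regime labels for a bin of a sweep (internal)
bin_regimes <- function(sweep, breaks, window, observable = "frac_AMBRA1_P") {
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  lab <- character(length(mids))
  for (b in seq_along(mids)) {
    sel <- sweep$input >= breaks[b] & sweep$input <= breaks[b + 1]
    if (!any(sel)) { lab[b] <- NA_character_; next }
    if (!is.null(window) && mids[b] >= window[1] && mids[b] <= window[2]) {
      lab[b] <- "oscillatory"
    } else {
      lab[b] <- if (mean(sweep[[observable]][sel]) > 0.5) "autophagy"
                else "translation"
    }
  }
  lab
}

#' Two-parameter regime diagram
#'
#' For each value of the second parameter (`y_param`), performs slow-drift
#' sweep(s) of the first (`x_param`) and classifies each cell of the x-grid
#' into a regime.  With `mode = "oscillation"` (the feedback model) an
#' up-sweep is analysed for its oscillation window; with
#' `mode = "bistability"` (the no-feedback model) an up/down sweep pair is
#' analysed for hysteresis.
#'
#' @param network A `reaction_network`.
#' @param x_param,x_range Drifted input (`"AMPK"` or `"rapa"`) and its range.
#' @param y_param Second parameter: `"AMPK"`, `"rapa"`, or a rate-constant
#'   name (e.g. `"p9"`).
#' @param y_values Grid values of the second parameter.
#' @param mode `"oscillation"` or `"bistability"`.
#' @param nbins Number of x-grid cells.
#' @param ... Passed to [oscillation_window()] / [detect_bistability()].
#' @return A `diagram2d` data frame with columns `x_lo`, `x_hi`, `x_mid`,
#'   `y`, `regime` (one of `"monostable-translation"`,
#'   `"monostable-autophagy"`, `"bistable"`, `"oscillatory"`).
#' @export
two_param_diagram <- function(network, x_param, x_range, y_param, y_values,
                              mode = c("oscillation", "bistability"),
                              nbins = 40, ...) {
  mode <- match.arg(mode)
  breaks <- seq(x_range[1], x_range[2], length.out = nbins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  rows <- list()
  for (yv in y_values) {
    net2 <- network
    fixed_ampk <- NULL; fixed_rapa <- NULL
    if (y_param %in% names(.input_types)) {
      if (.input_types[[y_param]] == "AMPK") fixed_ampk <- yv else fixed_rapa <- yv
    } else {
      net2 <- network_with_params(network, stats::setNames(list(yv), y_param))
    }
    up <- slow_drift_sweep(net2, sweep_config(x_param, x_range, "up"),
                           fixed_ampk = fixed_ampk, fixed_rapa = fixed_rapa)
    if (mode == "oscillation") {
      w <- oscillation_window(up, ...)
      lab <- bin_regimes(up, breaks, w)
      lab[lab == "autophagy"] <- "monostable-autophagy"
      lab[lab == "translation"] <- "monostable-translation"
    } else {
      down <- slow_drift_sweep(net2, sweep_config(x_param, x_range, "down"),
                               fixed_ampk = fixed_ampk, fixed_rapa = fixed_rapa)
      bi <- detect_bistability(up, down, ...)
      lab <- bin_regimes(up, breaks, NULL)
      lab[lab == "autophagy"] <- "monostable-autophagy"
      lab[lab == "translation"] <- "monostable-translation"
      if (nrow(bi)) {
        for (j in seq_len(nrow(bi)))
          lab[mids >= bi$lo[j] & mids <= bi$hi[j]] <- "bistable"
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      x_lo = breaks[-length(breaks)], x_hi = breaks[-1], x_mid = mids,
      y = yv, regime = lab, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("diagram2d", "data.frame")
  out
}
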