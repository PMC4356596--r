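# One-at-a-time parameter robustness analysis: classify the canonical
# three-regime response pattern (translation at low stress, oscillations at
# intermediate stress, autophagy at high stress) along input scans, and find
# the multiplier range over which each rate constant preserves it.

# the rate constants scanned by the robustness analysis (all except p9,
# whose influence is mapped separately in the two-parameter diagrams)
#' @rdname full_sensitivity
#' @export
sensitivity_parameters <- function() {
  c("a1", "a2", "a3", "a4", "a5", "d1", "d2", "d3", "d3max", "d4", "d5",
    "p1", "p2", "p3", "p4", "p5", "p6", "p7", "p8", "u0", "u1", "u2")
}

#' The 17-point multiplier grid of the robustness scan
#'
#' Multipliers 10^(n/4) for n = -8..8: 100-fold below to 100-fold above the
#' nominal value in quarter-decade steps.
#'
#' @return Numeric vector of 17 multipliers (the nominal multiplier 1 is the
#'   9th).
#' @export
sensitivity_multipliers <- function() 10^(seq(-8, 8) / 4)

#' Classify the response pattern along a stress-input scan
#'
#' Performs a slow-drift up-sweep of the input over its scan range — the
#' response of the system to a slowly rising stress — and tests for the
#' canonical ordered pattern: a translation regime (AMBRA1-P fraction below
#' 0.5) at low input, a non-degenerate oscillatory window at intermediate
#' input, and an autophagy regime (fraction above 0.5) at high input.
#' A monotonic graded response, or an abrupt switch without sustained
#' oscillations, is non-canonical.
#'
#' @param network A `reaction_network` (feedback model).
#' @param input `"AMPK"` (scan 0..1e6 copies/cell at zero rapamycin*) or
#'   `"rapa"` (scan 0..1e5 copies/cell at AMPK* = 30,000).
#' @param range Optional override of the scan range.
#' @param prominence Oscillation amplitude threshold.
#' @param margin Input margin (fraction of range) between the oscillation
#'   window and the steady regimes.
#' @param keep_sweep Attach the underlying sweep to the result.
#' @param probe When the sweep itself shows no oscillation window, probe a
#'   few fixed input levels around the translation-to-autophagy transition
#'   with [detect_limit_cycle()], starting from the swept state: oscillatory
#'   windows that are too narrow (or whose period is too long) for the drift
#'   to resolve are still detected.
#' @return A `response_pattern`: list with `canonical`, `window`, `regimes`
#'   (ordered labels actually observed), and optionally `sweep`.
#' @export
classify_response <- function(network, input = c("AMPK", "rapa"), range = NULL,
                              prominence = 0.01, margin = 0.02,
                              keep_sweep = FALSE, probe = TRUE) {
  input <- match.arg(input)
  if (is.null(range)) range <- if (input == "AMPK") c(0, 1e6) else c(0, 1e5)
  fixed_ampk <- if (input == "AMPK") NULL else 3e4
  fixed_rapa <- if (input == "AMPK") 0 else NULL
  sweep <- slow_drift_sweep(network, sweep_config(input, range, "up"),
                            fixed_ampk = fixed_ampk, fixed_rapa = fixed_rapa)
  w <- oscillation_window(sweep, prominence = prominence)
  f <- sweep$frac_AMBRA1_P
  mrg <- margin * diff(range)
  regimes <- character(0)
  canonical <- FALSE
  if (is.null(w) && probe)
    w <- probe_hidden_window(network, sweep, prominence)
  if (is.null(w)) {
    # no oscillatory window: graded or switch-like monotone response
    regimes <- unique(ifelse(f > 0.5, "autophagy", "translation"))
  } else {
    pre <- f[sweep$input < w[1] - mrg]
    post <- f[sweep$input > w[2] + mrg]
    has_translation <- length(pre) > 0 && max(pre) < 0.5
    has_autophagy <- length(post) > 0 && min(post) > 0.5
    regimes <- c(if (length(pre)) (if (max(pre) < 0.5) "translation" else "mixed"),
                 "oscillatory",
                 if (length(post)) (if (min(post) > 0.5) "autophagy" else "mixed"))
    canonical <- has_translation && has_autophagy
  }
  structure(list(canonical = canonical, window = w, regimes = regimes,
                 input = input, range = range,
                 sweep = if (keep_sweep) sweep else NULL),
            class = "response_pattern")
}

# Probe fixed input levels near the translation-to-autophagy transition of a
# sweep for limit cycles that the drift could not resolve (narrow windows
# with long-period cycles).  Probes start from the swept state at the probe
# input, mirroring the response-to-slowly-rising-stress protocol.
probe_hidden_window <- function(network, sweep, prominence,
                                offsets = c(-0.03, -0.015, -0.005, 0.005, 0.02)) {
  f <- stats::runmed(sweep$frac_AMBRA1_P, 9)
  cross <- which(f > 0.5)[1]
  if (is.na(cross)) return(NULL)
  x0 <- sweep$input[cross]
  states <- attr(sweep, "states")
  rng <- range(sweep$input)
  found <- c()
  for (off in offsets) {
    xp <- x0 + off * diff(rng)
    if (xp <= rng[1] || xp >= rng[2]) next
    i <- which.min(abs(sweep$input - xp))
    lc <- detect_limit_cycle(network, y0 = states[i, ],
                             amp_threshold = prominence, max_windows = 4)
    if (isTRUE(lc$oscillating)) found <- c(found, sweep$input[i])
  }
  if (!length(found)) return(NULL)
  range(found)
}

#' @export
print.response_pattern <- function(x, ...) {
  cat(sprintf("response to %s scan [%g, %g]: %s (%s)\n", x$input,
              x$range[1], x$range[2], paste(x$regimes, collapse = " -> "),
              if (x$canonical) "canonical" else "non-canonical"))
  invisible(x)
}

# canonical-on-both-scans predicate with caching; mult == 1 is shared across
# parameters
canonical_both <- function(network, param, mult, nominal, cache = NULL) {
  key <- if (mult == 1) "nominal" else paste(param, format(mult, digits = 12),
                                             sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  net2 <- if (mult == 1) network else
    network_with_params(network, stats::setNames(list(nominal * mult), param))
  ok <- classify_response(net2, "AMPK")$canonical &&
    classify_response(net2, "rapa")$canonical
  if (!is.null(cache)) cache[[key]] <- ok
  ok
}

#' Robustness range of one rate constant
#'
#' Finds the largest contiguous run of scan multipliers, containing the
#' nominal multiplier 1, for which the canonical response pattern holds on
#' both the AMPK* scan and the rapamycin* scan.  Multipliers outside the
#' first failure in each direction are not evaluated.
#'
#' @param network The expanded nominal `reaction_network`.
#' @param param Rate-constant name (one of [sensitivity_parameters()]).
#' @param multipliers Multiplier grid (must include 1); default the 17-point
#'   grid of [sensitivity_multipliers()].
#' @param cache Optional environment for memoising scan classifications
#'   across parameters (restartable sweeps).
#' @return List with `param`, `lo`, `hi` (multiplier bounds of the canonical
#'   run), `n_ok`, `fully_robust`, and `ok` (per-multiplier status; NA =
#'   not evaluated).
#' @export
robustness_range <- function(network, param,
                             multipliers = sensitivity_multipliers(),
                             cache = NULL) {
  if (!param %in% names(network$model$params))
    stop("unknown parameter: ", param)
  i0 <- which(abs(multipliers - 1) < 1e-12)
  if (length(i0) != 1L)
    stop("multiplier grid must contain the nominal multiplier 1 exactly once")
  nominal <- network$model$params[[param]]
  ok <- rep(NA, length(multipliers))
  ok[i0] <- canonical_both(network, param, 1, nominal, cache)
  if (!ok[i0])
    return(list(param = param, lo = NA_real_, hi = NA_real_, n_ok = 0L,
                fully_robust = FALSE, ok = ok,
                diagnostic = "nominal model is not canonical"))
  hi_idx <- i0
  while (hi_idx < length(multipliers)) {
    res <- canonical_both(network, param, multipliers[hi_idx + 1L], nominal, cache)
    ok[hi_idx + 1L] <- res
    if (!res) break
    hi_idx <- hi_idx + 1L
  }
  lo_idx <- i0
  while (lo_idx > 1L) {
    res <- canonical_both(network, param, multipliers[lo_idx - 1L], nominal, cache)
    ok[lo_idx - 1L] <- res
    if (!res) break
    lo_idx <- lo_idx - 1L
  }
  list(param = param, lo = multipliers[lo_idx], hi = multipliers[hi_idx],
       n_ok = hi_idx - lo_idx + 1L,
       fully_robust = lo_idx == 1L && hi_idx == length(multipliers),
       ok = ok)
}

#' Full one-at-a-time robustness scan
#'
#' Runs [robustness_range()] for every rate constant of the model except
#' `p9`, on the 17-point multiplier grid (or a reduced grid in quick mode),
#' and reports the per-parameter canonical ranges (the robustness bars) and
#' the number of fully robust parameters.
#'
#' @param network The expanded nominal `reaction_network`.
#' @param params Parameters to scan; default all 22.
#' @param multipliers Multiplier grid; default 17 points, or
#'   `10^(c(-8,-3,0,3,8)/4)` when `quick = TRUE`.
#' @param quick Reduced 5-point grid for fast scans.
#' @param verbose Print progress.
#' @return List with `table` (data frame: parameter, lo, hi, n_ok,
#'   fully_robust) and `n_fully_robust`.
#' @export
full_sensitivity <- function(network, params = sensitivity_parameters(),
                             multipliers = NULL, quick = FALSE,
                             verbose = FALSE) {
  if (is.null(multipliers))
    multipliers <- if (quick) 10^(c(-8, -3, 0, 3, 8) / 4)
                   else sensitivity_multipliers()
  cache <- new.env(parent = emptyenv())
  rows <- lapply(params, function(p) {
    r <- robustness_range(network, p, multipliers, cache = cache)
    if (verbose)
      message(sprintf("%-6s [%g, %g] %s", p, r$lo, r$hi,
                      if (r$fully_robust) "fully robust" else ""))
    data.frame(parameter = p, lo = r$lo, hi = r$hi, n_ok = r$n_ok,
               fully_robust = r$fully_robust, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, n_fully_robust = sum(tab$fully_robust),
       multipliers = multipliers)
}
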