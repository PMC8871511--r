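#' Parameters of the elementary two-tanh map unit
#'
#' The elementary dynamical unit is the discrete-time scalar map
#' \deqn{x(t+1) = a_1 \tanh(a_2 (x(t) - a_3)) - a_4 \tanh(a_5 (x(t) - a_6)) + b.}
#' Depending on the parameters the map graph is monotone, unimodal or
#' bimodal, and the iterated dynamics realise a passively susceptible
#' fixed point, an excitable (spiking) transient, or a sustained
#' oscillation.
#'
#' @param a1,a4 amplitudes of the two tanh branches (dimensionless reals).
#' @param a2,a5 gains of the two branches; must be non-negative.
#' @param a3,a6 thresholds (branch centres).
#' @param b additive bias.
#'
#' @return An object of class `elementary_params`.
#' @examples
#' p <- elementary_params(a1 = 1, a2 = 5, b = 0.1)
#' elementary_map(0, p)
#' @export
elementary_params <- function(a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0,
                              a6 = 0, b = 0) {
  vals <- c(a1 = a1, a2 = a2, a3 = a3, a4 = a4, a5 = a5, a6 = a6, b = b)
  if (!all(is.finite(vals))) {
    stop("elementary_params: all parameters must be finite")
  }
  if (a2 < 0 || a5 < 0) {
    stop("elementary_params: gains a2 and a5 must be >= 0")
  }
  structure(as.list(vals), class = "elementary_params")
}

#' @export
print.elementary_params <- function(x, ...) {
  cat("elementary map unit: a = (",
      paste(signif(unlist(x[1:6]), 4), collapse = ", "),
      "), b =", signif(x$b, 4), "\n")
  invisible(x)
}

#' Evaluate the elementary map
#'
#' @param x numeric vector of states.
#' @param p an [elementary_params()] object.
#' @return `a1*tanh(a2*(x - a3)) - a4*tanh(a5*(x - a6)) + b`, vectorised
#'   over `x`. The result is always bounded by `|a1| + |a4| + |b|`.
#' @export
elementary_map <- function(x, p) {
  stopifnot(inherits(p, "elementary_params"))
  if (!all(is.finite(x))) stop("elementary_map: x must be finite")
  p$a1 * tanh(p$a2 * (x - p$a3)) - p$a4 * tanh(p$a5 * (x - p$a6)) + p$b
}

#' Classify the shape of the elementary map graph
#'
#' Classifies the graph of [elementary_map()] over an interval as
#' `"monotone"`, `"unimodal"`, `"bimodal"`, `"constant"` or `"other"` by
#' counting sign changes of first differences on an evaluation grid.
#'
#' @param p an [elementary_params()] object.
#' @param interval length-2 numeric, the evaluation interval.
#' @param grid number of grid points (>= 16).
#' @param tol differences with absolute value below `tol` count as flat.
#' @return A character scalar shape label.
#' @export
map_shape <- function(p, interval = c(-3, 3), grid = 256, tol = 1e-12) {
  if (length(interval) != 2 || !all(is.finite(interval)) ||
      interval[2] <= interval[1]) {
    stop("map_shape: interval must be a finite increasing pair")
  }
  if (grid < 16) stop("map_shape: grid must be >= 16")
  xs <- seq(interval[1], interval[2], length.out = grid)
  d <- diff(elementary_map(xs, p))
  s <- sign(d)
  s[abs(d) < tol] <- 0
  s <- s[s != 0]
  if (length(s) == 0) return("constant")
  changes <- sum(diff(s) != 0)
  if (changes == 0) "monotone"
  else if (changes == 1) "unimodal"
  else if (changes == 2) "bimodal"
  else "other"
}

#' Probe protocol for dynamical-state classification
#'
#' Settings for [classify_unit_state()]: how long to iterate before
#' observing, how large a probe pulse to inject, and the numerical
#' thresholds that separate the dynamical regimes.
#'
#' @param transient iterations discarded before observation.
#' @param observe iterations observed (autonomous run and pulse response).
#' @param pulse amplitude of the single probe pulse added to the rest state.
#' @param eps_fp tolerance for "returned to rest" (fixed-point tolerance).
#' @param eps_osc peak-to-peak amplitude above which the autonomous orbit
#'   counts as non-stationary.
#' @param overshoot_ratio response peak must exceed `overshoot_ratio *
#'   pulse` for an excitable classification.
#' @param recurrence_tol tolerance of the orbit-recurrence period detector.
#' @return An object of class `classify_protocol`.
#' @export
classify_protocol <- function(transient = 500, observe = 500, pulse = 0.5,
                              eps_fp = 1e-4, eps_osc = 1e-3,
                              overshoot_ratio = 2.0, recurrence_tol = 1e-6) {
  structure(list(transient = transient, observe = observe, pulse = pulse,
                 eps_fp = eps_fp, eps_osc = eps_osc,
                 overshoot_ratio = overshoot_ratio,
                 recurrence_tol = recurrence_tol),
            class = "classify_protocol")
}

iterate_map <- function(x0, p, n) {
  out <- numeric(n)
  x <- x0
  for (t in seq_len(n)) {
    x <- elementary_map(x, p)
    out[t] <- x
  }
  out
}

detect_period <- function(orbit, tol) {
  L <- length(orbit)
  for (pp in 2:max(2, floor(L / 2))) {
    if (max(abs(orbit[seq_len(L - pp)] - orbit[seq_len(L - pp) + pp])) < tol) {
      return(pp)
    }
  }
  NA_integer_
}

#' Classify an isolated unit as passive, excitable or oscillatory
#'
#' Runs the uncoupled unit through a two-stage probe. First the autonomous
#' orbit: if, after the transient, its peak-to-peak amplitude exceeds
#' `eps_osc` and an orbit-recurrence period of at least 2 is detected, the
#' unit is `"oscillatory"`. Otherwise the unit has settled to a rest state
#' and a single pulse is injected: a response whose peak deviation exceeds
#' `overshoot_ratio * pulse` before returning within `eps_fp` of rest is
#' `"excitable"` (regenerative amplification); a response whose peak stays
#' at or below the pulse and decays monotonically is `"passive"`. Anything
#' else (aperiodic large-amplitude orbits, non-returning or non-monotone
#' responses) is `"other"`.
#'
#' @param p an [elementary_params()] object.
#' @param protocol a [classify_protocol()].
#' @param x0 initial condition for the autonomous run; slightly off zero
#'   by default so unstable equilibria do not mask an oscillation.
#' @return A list of class `unit_state` with `category` and a named
#'   `evidence` vector (autonomous amplitude, detected period, response
#'   peak, response gain, return time).
#' @export
classify_unit_state <- function(p, protocol = classify_protocol(), x0 = 1e-3) {
  pr <- protocol
  warm <- x0
  for (t in seq_len(pr$transient)) warm <- elementary_map(warm, p)
  orbit <- iterate_map(warm, p, pr$observe)
  amp <- max(orbit) - min(orbit)
  evidence <- c(autonomous_amplitude = amp, period = NA_real_,
                response_peak = NA_real_, response_gain = NA_real_,
                return_time = NA_real_)

  if (amp > pr$eps_osc) {
    per <- detect_period(orbit, pr$recurrence_tol)
    evidence["period"] <- per
    if (!is.na(per) && per >= 2) {
      return(structure(list(category = "oscillatory", evidence = evidence),
                       class = "unit_state"))
    }
    return(structure(list(category = "other", evidence = evidence),
                     class = "unit_state"))
  }

  rest <- orbit[length(orbit)]
  resp <- iterate_map(rest + pr$pulse, p, pr$observe)
  dev <- abs(c(pr$pulse, resp - rest))
  peak <- max(dev)
  evidence["response_peak"] <- peak
  evidence["response_gain"] <- peak / pr$pulse
  ret <- which(dev < pr$eps_fp)
  evidence["return_time"] <- if (length(ret)) ret[1] - 1 else NA_real_

  category <- if (peak > pr$overshoot_ratio * pr$pulse && length(ret) > 0) {
    "excitable"
  } else if (peak <= pr$pulse + pr$eps_fp && all(diff(dev) <= pr$eps_fp)) {
    "passive"
  } else {
    "other"
  }
  structure(list(category = category, evidence = evidence),
            class = "unit_state")
}

#' @export
print.unit_state <- function(x, ...) {
  cat("unit state:", x$category, "\n")
  ev <- x$evidence[!is.na(x$evidence)]
  if (length(ev)) {
    cat(paste0("  ", names(ev), " = ", signif(ev, 4), collapse = "\n"), "\n")
  }
  invisible(x)
}
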