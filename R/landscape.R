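#' One-dimensional polynomial landscape
#'
#' A scalar potential over a state variable `y`, represented by its
#' coefficient vector for powers `0..P`. Local minima of the landscape
#' are the attractors of the gradient dynamics and model differentiated
#' (metastable) states; changes of the basin structure along a
#' coefficient path model differentiation events.
#'
#' @param coeffs numeric coefficients for powers `0..P` of `y`.
#' @param interval length-2 numeric evaluation interval.
#' @param grid grid resolution used by the attractor scan (>= 64).
#' @return An object of class `poly_landscape`.
#' @export
poly_landscape <- function(coeffs, interval = c(-3, 3), grid = 1024) {
  stopifnot(length(coeffs) >= 2, all(is.finite(coeffs)),
            length(interval) == 2, interval[1] < interval[2], grid >= 64)
  structure(list(coeffs = as.numeric(coeffs), interval = as.numeric(interval),
                 grid = as.integer(grid)),
            class = "poly_landscape")
}

#' @export
print.poly_landscape <- function(x, ...) {
  cat("poly_landscape: degree", length(x$coeffs) - 1, "on [",
      x$interval[1], ",", x$interval[2], "]\n")
  invisible(x)
}

#' Evaluate a landscape (or any coefficient vector) by Horner's rule
#'
#' @param L a [poly_landscape()] or a bare coefficient vector (powers
#'   `0..P`).
#' @param y numeric vector of states.
#' @return Landscape values at `y`.
#' @export
eval_landscape <- function(L, y) {
  cf <- if (inherits(L, "poly_landscape")) L$coeffs else L
  out <- rep(cf[length(cf)], length(y))
  for (i in rev(seq_len(length(cf) - 1))) out <- out * y + cf[i]
  out
}

poly_deriv <- function(coeffs) {
  p <- length(coeffs) - 1
  if (p == 0) return(0)
  coeffs[-1] * seq_len(p)
}

#' Single-attractor stem landscape
#'
#' `S(y; b) = y^n + b y + 1`: an even-degree well whose single tilt
#' parameter `b` models the activation state of an undifferentiated
#' (stem) cell.
#'
#' @param y numeric state values.
#' @param b tilt coefficient.
#' @param n polynomial degree (>= 2).
#' @return `y^n + b*y + 1`.
#' @export
landscape_S <- function(y, b, n = 4) {
  stopifnot(is.finite(b), n >= 2)
  y^n + b * y + 1
}

#' Coefficient vector of the stem landscape
#'
#' @inheritParams landscape_S
#' @return Coefficients (powers `0..n`) such that
#'   `eval_landscape(coeffs, y) == landscape_S(y, b, n)`.
#' @export
landscape_S_coeffs <- function(b, n = 4) {
  cf <- numeric(n + 1)
  cf[1] <- 1
  cf[2] <- b
  cf[n + 1] <- 1
  cf
}

#' Stem-cell activation table h(b)
#'
#' Tabulates the stem landscape as a function of its single parameter:
#' `h(b) = S(. ; b)` evaluated on a `y` grid. Two calls with equal `b`
#' are identical; the table is Lipschitz in `b` with constant
#' `max |y|` over the grid.
#'
#' @param b tilt coefficient.
#' @param n polynomial degree.
#' @param y numeric evaluation grid.
#' @return Data frame (`y`, `S`) with attributes `b`, `n`, `grid`.
#' @export
stem_index <- function(b, n = 4, y = seq(-2, 2, length.out = 256)) {
  out <- data.frame(y = y, S = landscape_S(y, b, n))
  attr(out, "b") <- b
  attr(out, "n") <- n
  attr(out, "grid") <- length(y)
  out
}

#' Multi-attractor differentiated landscape
#'
#' `D(y; c_1..c_n) = y^confine + sum_i c_i y^i`: the coefficient vector
#' plays the role of an n-variable index of the differentiated state,
#' and a confining even leading monomial of degree `confine > n`
#' guarantees that minima exist.
#'
#' @param y numeric state values.
#' @param c_coeffs coefficients `c_1..c_n` of powers `1..n`.
#' @param confine even confining degree (`> length(c_coeffs)`).
#' @return Landscape values.
#' @export
landscape_D <- function(y, c_coeffs, confine = 2 * ((length(c_coeffs) + 2) %/% 2)) {
  n <- length(c_coeffs)
  if (confine %% 2 != 0) stop("landscape_D: confining degree must be even")
  if (confine <= n) stop("landscape_D: confining degree must exceed n")
  eval_landscape(landscape_D_coeffs(c_coeffs, confine), y)
}

#' @rdname landscape_D
#' @export
landscape_D_coeffs <- function(c_coeffs, confine = 2 * ((length(c_coeffs) + 2) %/% 2)) {
  n <- length(c_coeffs)
  cf <- numeric(confine + 1)
  cf[1 + seq_len(n)] <- c_coeffs
  cf[confine + 1] <- cf[confine + 1] + 1
  cf
}

#' Count the attractors (interior local minima) of a landscape
#'
#' Scans the landscape on its grid for sign changes of the first
#' differences from negative to positive, refines each bracketed
#' stationary point by root-finding on the analytic derivative, and
#' returns the interior minima. Minima sitting on the interval boundary
#' are flagged separately, not counted.
#'
#' @param L a [poly_landscape()].
#' @return An object of class `attractor_set`: `minima` (data frame
#'   `location`, `value`), `count`, `boundary` (character subset of
#'   `"left"`, `"right"`).
#' @export
count_attractors <- function(L) {
  stopifnot(inherits(L, "poly_landscape"))
  ys <- seq(L$interval[1], L$interval[2], length.out = L$grid)
  v <- eval_landscape(L, ys)
  d <- diff(v)
  s <- sign(d)
  dcf <- poly_deriv(L$coeffs)
  # scan sign transitions of the first differences, skipping flat steps
  # (a minimum can fall exactly on a grid point, giving -, 0, +)
  nz <- which(s != 0)
  locs <- c()
  if (length(nz) >= 2) {
    for (j in seq_len(length(nz) - 1)) {
      i1 <- nz[j]; i2 <- nz[j + 1]
      if (s[i1] < 0 && s[i2] > 0) {
        lo <- ys[i1]; hi <- ys[i2 + 1]
        flo <- eval_landscape(dcf, lo); fhi <- eval_landscape(dcf, hi)
        root <- if (is.finite(flo) && is.finite(fhi) && flo < 0 && fhi > 0) {
          stats::uniroot(function(y) eval_landscape(dcf, y), c(lo, hi),
                         tol = 1e-12)$root
        } else {
          (lo + hi) / 2
        }
        locs <- c(locs, root)
      }
    }
  }
  boundary <- c(if (length(nz) && s[nz[1]] > 0) "left",
                if (length(nz) && s[nz[length(nz)]] < 0) "right")
  minima <- data.frame(location = locs %||% numeric(0),
                       value = eval_landscape(L, locs %||% numeric(0)))
  structure(list(minima = minima, count = nrow(minima),
                 boundary = boundary %||% character(0)),
            class = "attractor_set")
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("attractor_set:", x$count, "interior minima")
  if (x$count) cat(" at", paste(signif(x$minima$location, 4), collapse = ", "))
  if (length(x$boundary)) cat(" ( boundary:", paste(x$boundary, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

#' Explicit gradient descent on a landscape
#'
#' Iterates `y <- y - step * L'(y)`. For admissible steps the landscape
#' value is non-increasing along the trajectory; the basin label is the
#' nearest attractor at convergence, or `"escaped"` if the trajectory
#' leaves the interval.
#'
#' @param L a [poly_landscape()].
#' @param y0 initial state.
#' @param step descent step (default `1e-3` of the interval width).
#' @param iters maximum iterations.
#' @param tol gradient magnitude declaring convergence.
#' @return List: `trajectory`, `y_final`, `basin` (index into
#'   `count_attractors(L)$minima` or `"escaped"`), `converged`.
#' @export
gradient_flow <- function(L, y0, step = 1e-3 * diff(L$interval),
                          iters = 10000, tol = 1e-10) {
  stopifnot(inherits(L, "poly_landscape"), step > 0)
  dcf <- poly_deriv(L$coeffs)
  y <- y0
  traj <- numeric(0)
  escaped <- FALSE
  for (i in seq_len(iters)) {
    g <- eval_landscape(dcf, y)
    y <- y - step * g
    traj <- c(traj, y)
    if (y < L$interval[1] || y > L$interval[2]) { escaped <- TRUE; break }
    if (abs(g) < tol) break
  }
  att <- count_attractors(L)
  basin <- if (escaped || att$count == 0) "escaped" else {
    which.min(abs(att$minima$location - y))
  }
  list(trajectory = traj, y_final = y, basin = basin,
       converged = !escaped && abs(eval_landscape(dcf, y)) < sqrt(tol))
}

#' Attractor-count profile along a coefficient path
#'
#' Interpolates linearly between two coefficient vectors and counts the
#' attractors of the interpolated landscape at each step, reporting
#' where the count changes (bifurcation indices of the morph).
#'
#' @param start,end coefficient vectors of equal length (powers `0..P`).
#' @param steps number of path points (including the endpoints).
#' @param interval,grid landscape evaluation settings.
#' @return Data frame of class `differentiation_path` with columns
#'   `step`, `alpha`, `count`; attribute `transitions` lists the steps
#'   at which the count changes.
#' @export
differentiation_path <- function(start, end, steps = 50,
                                 interval = c(-3, 3), grid = 1024) {
  stopifnot(length(start) == length(end), steps >= 2)
  alphas <- seq(0, 1, length.out = steps)
  counts <- vapply(alphas, function(a) {
    cf <- (1 - a) * start + a * end
    count_attractors(poly_landscape(cf, interval, grid))$count
  }, numeric(1))
  out <- data.frame(step = seq_len(steps), alpha = alphas, count = counts)
  attr(out, "transitions") <- which(diff(counts) != 0) + 1L
  class(out) <- c("differentiation_path", "data.frame")
  out
}

#' Superposition index transform of landscape coefficients
#'
#' Applies the tabulated inner function to each landscape index
#' (coefficient) and returns both the transformed indices
#' `psi(c_1)..psi(c_n)` — interpreted as stem-cell activation states
#' shared by every differentiated landscape — and the inner-map image
#' `z`, which is injective on the grid so distinct index vectors keep
#' distinct representations.
#'
#' @param c_vec numeric index vector in `[0, 1]^n`.
#' @param params a [kas_constants()] object with matching `n`.
#' @param table an [inner_psi()] table.
#' @return List: `psi` (transformed indices), `z` (inner-map image).
#' @export
index_transform <- function(c_vec, params, table) {
  if (any(c_vec < 0 | c_vec > 1)) {
    stop("index_transform: indices must lie in [0, 1]")
  }
  if (length(c_vec) != params$n) {
    stop("index_transform: expected n = ", params$n, " indices")
  }
  list(psi = psi_eval(table, c_vec),
       z = inner_map(c_vec, params, table))
}
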