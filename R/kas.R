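#' Digit-weight exponent of the superposition construction
#'
#' `beta_n(n, l) = (1 - n^l) / (1 - n) = 1 + n + ... + n^(l-1)`, the
#' exponent controlling how fast the inner-function digit weights
#' `gamma^(-beta_n(l))` shrink with grid depth `l`.
#'
#' @param n input dimension (>= 2).
#' @param l depth index (>= 1), vectorised.
#' @return Numeric vector of `beta_n` values.
#' @export
beta_n <- function(n, l) {
  stopifnot(n >= 2)
  if (any(l < 1)) stop("beta_n: depth index l must be >= 1")
  (1 - n^l) / (1 - n)
}

#' Constants of the constructive superposition representation
#'
#' For admissible integers `n >= 2`, `m >= 2n`, `gamma >= m + 2`,
#' computes the constants of the superposition
#' `f(x) = sum_j phi_j(sum_i lambda_i psi(x_i + j c))`:
#' `c = 1 / (gamma (gamma - 1))`, `lambda_1 = 1`,
#' `lambda_i = sum_l gamma^(-(i-1) beta_n(l))` (series truncated when a
#' term drops below `tol`), the Hoelder exponent `alpha = log_gamma 2`,
#' and the Hoelder constant `nu = 2^(-alpha) (gamma + 3)`.
#'
#' @param n input dimension.
#' @param m one less than the number of outer functions.
#' @param gamma integer base of the grid (`>= m + 2`).
#' @param tol truncation tolerance of the `lambda` series.
#' @return An object of class `kas_params` with fields `n`, `m`,
#'   `gamma`, `c`, `lambda` (length `n`), `alpha`, `nu`.
#' @export
kas_constants <- function(n, m, gamma, tol = 1e-16) {
  if (n != round(n) || n < 2) stop("kas_constants: need integer n >= 2")
  if (m != round(m) || m < 2 * n) {
    stop("kas_constants: admissibility violated: m >= 2n required (m = ",
         m, ", 2n = ", 2 * n, ")")
  }
  if (gamma != round(gamma) || gamma < m + 2) {
    stop("kas_constants: admissibility violated: gamma >= m + 2 required (gamma = ",
         gamma, ", m + 2 = ", m + 2, ")")
  }
  lambda <- numeric(n)
  lambda[1] <- 1
  if (n >= 2) {
    for (i in 2:n) {
      s <- 0
      l <- 1
      repeat {
        term <- gamma^(-(i - 1) * beta_n(n, l))
        if (!is.finite(term) || term < tol) break
        s <- s + term
        l <- l + 1
      }
      lambda[i] <- s
    }
  }
  alpha <- log(2) / log(gamma)
  structure(list(n = as.integer(n), m = as.integer(m),
                 gamma = as.integer(gamma),
                 c = 1 / (gamma * (gamma - 1)),
                 lambda = lambda,
                 alpha = alpha,
                 nu = 2^(-alpha) * (gamma + 3)),
            class = "kas_params")
}

#' @export
print.kas_params <- function(x, ...) {
  cat("kas_params: n =", x$n, ", m =", x$m, ", gamma =", x$gamma,
      "\n  c =", signif(x$c, 6), ", lambda =",
      paste(signif(x$lambda, 8), collapse = ", "),
      "\n  alpha =", signif(x$alpha, 6), ", nu =", signif(x$nu, 6), "\n")
  invisible(x)
}

#' Tabulated monotone inner function on the depth-k grid
#'
#' Builds the self-similar inner function `psi : [0, 2] -> [0, 2]` on
#' the base-`gamma` rational grid of depth `k` (spacing `gamma^-k`). For
#' a grid point `d = sum_r i_r gamma^-r` in `[0, 1)` the value is the
#' digit sum `psi(d) = sum_r i_r gamma^(-beta_n(r))`; the function is
#' extended to `[1, 2]` by the unit translation `psi(1 + u) = 1 +
#' psi(u)`. Between grid points the table interpolates linearly. The
#' construction is strictly increasing on the grid, maps into `[0, 2]`,
#' is refinement-consistent (depth-`k` values reappear unchanged at
#' depth `k + 1`) and satisfies the `(nu, alpha)`-Hoelder bound checked
#' by [check_holder()].
#'
#' @param gamma integer base (>= 2).
#' @param n input dimension (>= 2), entering through the digit weights.
#' @param k grid depth (>= 1); the precision is `gamma^-k`.
#' @return An object of class `inner_function_table` with fields `x`,
#'   `psi` (sorted, equal length), `gamma`, `n`, `k`.
#' @export
inner_psi <- function(gamma, n, k) {
  stopifnot(gamma == round(gamma), gamma >= 2, n >= 2, k >= 1)
  G <- gamma^k
  if (G > 1e7) stop("inner_psi: grid too large (gamma^k > 1e7)")
  j <- 0:(G - 1)
  # digit matrix: column r holds digit i_r of j * gamma^-k
  digits <- matrix(0L, length(j), k)
  rem <- j
  for (r in seq_len(k)) {
    p <- gamma^(k - r)
    digits[, r] <- rem %/% p
    rem <- rem %% p
  }
  w <- gamma^(-beta_n(n, seq_len(k)))
  psi01 <- drop(digits %*% w)
  x <- c(j / G, 1 + j / G, 2)
  psi <- c(psi01, 1 + psi01, 2)
  structure(list(x = x, psi = psi, gamma = as.integer(gamma),
                 n = as.integer(n), k = as.integer(k)),
            class = "inner_function_table")
}

#' @export
print.inner_function_table <- function(x, ...) {
  cat("inner_function_table: gamma =", x$gamma, ", n =", x$n,
      ", depth k =", x$k, "(", length(x$x), "grid points on [0, 2] )\n")
  invisible(x)
}

#' Evaluate the tabulated inner function by linear interpolation
#'
#' @param table an [inner_psi()] table.
#' @param x numeric values in `[0, 2]`.
#' @return `psi(x)` interpolated linearly between grid points.
#' @export
psi_eval <- function(table, x) {
  if (any(x < -1e-12 | x > 2 + 1e-12)) {
    stop("psi_eval: arguments outside [0, 2]")
  }
  stats::approx(table$x, table$psi, xout = pmin(pmax(x, 0), 2),
                method = "linear", ties = "ordered")$y
}

#' Exhaustive / sampled Hoelder-continuity check
#'
#' Verifies `|psi(x) - psi(y)| <= nu |x - y|^alpha` over grid-point
#' pairs of the table: exhaustively when the table has at most
#' `max_exhaustive` points, otherwise on `n_random` random pairs.
#'
#' @param table an [inner_psi()] table.
#' @param nu,alpha Hoelder constant and exponent.
#' @param max_exhaustive largest table size checked pair-exhaustively.
#' @param n_random number of random pairs beyond that size.
#' @param seed RNG seed for the sampled regime.
#' @return List: `pass`, `max_ratio` (worst `|d psi| / |d x|^alpha`),
#'   `worst_pair` (the maximizing `x` pair), `n_pairs`.
#' @export
check_holder <- function(table, nu, alpha, max_exhaustive = 1e4,
                         n_random = 1e6, seed = 1L) {
  x <- table$x
  ps <- table$psi
  L <- length(x)
  best <- c(ratio = -Inf, x1 = NA, x2 = NA)
  n_pairs <- 0
  if (L <= max_exhaustive) {
    block <- 500L
    for (i0 in seq(1L, L - 1L, by = block)) {
      ii <- i0:min(i0 + block - 1L, L - 1L)
      for (i in ii) {
        jj <- (i + 1L):L
        ratio <- abs(ps[jj] - ps[i]) / (x[jj] - x[i])^alpha
        n_pairs <- n_pairs + length(jj)
        mx <- which.max(ratio)
        if (ratio[mx] > best["ratio"]) {
          best <- c(ratio = ratio[mx], x1 = x[i], x2 = x[jj[mx]])
        }
      }
    }
  } else {
    set.seed(seed)
    i <- sample.int(L, n_random, replace = TRUE)
    j <- sample.int(L, n_random, replace = TRUE)
    keep <- i != j
    i <- i[keep]; j <- j[keep]
    ratio <- abs(ps[i] - ps[j]) / abs(x[i] - x[j])^alpha
    n_pairs <- length(ratio)
    mx <- which.max(ratio)
    best <- c(ratio = ratio[mx], x1 = x[i[mx]], x2 = x[j[mx]])
  }
  list(pass = best[["ratio"]] <= nu,
       max_ratio = best[["ratio"]],
       worst_pair = c(best[["x1"]], best[["x2"]]),
       n_pairs = n_pairs)
}

#' Inner map of the superposition: n-cube to m+1 coordinates
#'
#' Computes `z_j(x) = sum_i lambda_i psi(x_i + j c)` for `j = 0..m`.
#' On the depth-`k` grid this map is injective (checked exhaustively for
#' small instances by the test-suite), which is the structural property
#' that makes the superposition representation possible.
#'
#' @param x numeric vector of length `n` in `[0, 1]^n`, or a matrix with
#'   `n` columns (one point per row).
#' @param params a [kas_constants()] object.
#' @param table an [inner_psi()] table (same `gamma` and `n`).
#' @return Length-`m + 1` vector `z`, or a matrix with `m + 1` columns
#'   for matrix input.
#' @export
inner_map <- function(x, params, table) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != params$n) stop("inner_map: x must have n coordinates")
  if (any(X < -1e-12 | X > 1 + 1e-12)) stop("inner_map: x outside [0, 1]^n")
  Z <- matrix(0, nrow(X), params$m + 1)
  for (j in 0:params$m) {
    P <- matrix(psi_eval(table, as.vector(X) + j * params$c),
                nrow(X), params$n)
    Z[, j + 1] <- P %*% params$lambda
  }
  if (is.matrix(x)) Z else drop(Z)
}

#' Base-gamma evaluation grid on the unit cube
#'
#' The depth-`depth` grid `{j gamma^-depth}` in each coordinate
#' (including 1), or — with a fractional `offset` — the grid shifted by
#' `offset * gamma^-depth` (used for test points that avoid training
#' knots).
#'
#' @param n dimension.
#' @param gamma integer base.
#' @param depth grid depth.
#' @param offset fractional shift in units of the grid step.
#' @return Matrix with `n` columns, one grid point per row.
#' @export
kas_grid <- function(n, gamma, depth, offset = 0) {
  pts1 <- (0:(gamma^depth)) / gamma^depth
  if (offset != 0) {
    pts1 <- pts1[-length(pts1)] + offset / gamma^depth
  }
  as.matrix(expand.grid(rep(list(pts1), n)))
}

full_grid <- kas_grid

#' Empirical outer functions for a given target function
#'
#' Samples `f` on the depth-`depth` base-`gamma` grid of `[0, 1]^n` and
#' distributes the targets equally across the `m + 1` branches: branch
#' `j` receives the knot `(z_j(x), f(x) / (m + 1))` for every grid point
#' `x`. Each outer function `phi_j` is the piecewise-linear interpolant
#' through its sorted knots (exact duplicates averaged, evaluation
#' clamped to the observed argument range). Because the inner map is
#' injective on the grid, the reconstruction is exact at the training
#' points; off-grid quality is reported by [kas_reconstruct()], not
#' guaranteed.
#'
#' @param f function taking a matrix with `n` columns (points in rows)
#'   and returning a numeric vector; a plain `function(x1, x2, ...)` can
#'   be wrapped with [cube_function()].
#' @param params a [kas_constants()] object.
#' @param table an [inner_psi()] table.
#' @param depth sampling grid depth (default: the table's depth).
#' @return An object of class `outer_function_set`: list of `m + 1`
#'   interpolants plus the training grid metadata.
#' @export
fit_outer <- function(f, params, table, depth = table$k) {
  X <- full_grid(params$n, params$gamma, depth)
  fx <- f(X)
  if (!all(is.finite(fx))) stop("fit_outer: f returned non-finite values")
  share <- fx / (params$m + 1)
  Z <- inner_map(X, params, table)
  phis <- lapply(seq_len(params$m + 1), function(jj) {
    z <- Z[, jj]
    o <- order(z)
    zo <- z[o]; so <- share[o]
    grp <- cumsum(c(TRUE, diff(zo) > 0))
    zk <- zo[!duplicated(grp)]
    yk <- as.vector(rowsum(so, grp) / tabulate(grp))
    stats::approxfun(zk, yk, method = "linear", rule = 2, ties = "ordered")
  })
  structure(list(phi = phis, params = params, depth = depth,
                 n_train = nrow(X)),
            class = "outer_function_set")
}

#' Wrap an n-argument scalar function for grid evaluation
#'
#' @param fn a function of `n` scalar arguments, e.g.
#'   `function(x1, x2) x1 * x2`.
#' @return A function of a point matrix suitable for [fit_outer()].
#' @export
cube_function <- function(fn) {
  function(X) do.call(mapply, c(list(FUN = fn),
                                lapply(seq_len(ncol(X)), function(i) X[, i])))
}

#' Evaluate the fitted superposition
#'
#' @param outer an [fit_outer()] object.
#' @param x point matrix (rows) or single point in `[0, 1]^n`.
#' @param table the [inner_psi()] table used for fitting.
#' @return Reconstructed function values `sum_j phi_j(z_j(x))`.
#' @export
kas_eval <- function(outer, x, table) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  Z <- inner_map(X, outer$params, table)
  out <- numeric(nrow(X))
  for (jj in seq_len(outer$params$m + 1)) {
    out <- out + outer$phi[[jj]](Z[, jj])
  }
  out
}

#' Sup-norm reconstruction error of the superposition
#'
#' Fits the outer functions at the table's depth and evaluates the
#' reconstruction on a test grid offset by half a *training-grid* step
#' from the training points (so no test point coincides with a knot,
#' whatever the relative depths), returning the maximum absolute error.
#'
#' @param f target function (matrix form, see [cube_function()]).
#' @param params a [kas_constants()] object.
#' @param table an [inner_psi()] table.
#' @param test_depth depth of the offset test grid.
#' @param outer optionally, a pre-fitted [fit_outer()] object.
#' @return List: `sup_error`, `n_test`, `outer`.
#' @export
kas_reconstruct <- function(f, params, table, test_depth = 2,
                            outer = NULL) {
  if (is.null(outer)) outer <- fit_outer(f, params, table)
  shift <- if (table$k > test_depth) {
    0.5 * params$gamma^(test_depth - table$k)
  } else {
    0.5
  }
  Xt <- full_grid(params$n, params$gamma, test_depth, offset = shift)
  err <- abs(f(Xt) - kas_eval(outer, Xt, table))
  list(sup_error = max(err), n_test = nrow(Xt), outer = outer)
}

#' Rectified linear unit
#'
#' The activation `g(z) = max(0, z)` used by deep networks that realise
#' superposition representations.
#'
#' @param z numeric vector.
#' @return `pmax(0, z)`.
#' @export
relu <- function(z) {
  if (!all(is.finite(z))) stop("relu: z must be finite")
  pmax(0, z)
}

#' Write the inner-function table as CSV
#'
#' @param table an [inner_psi()] table.
#' @param path CSV path (columns `x,psi`).
#' @export
write_psi_csv <- function(table, path) {
  utils::write.csv(data.frame(x = table$x, psi = table$psi), path,
                   row.names = FALSE)
  invisible(table)
}
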