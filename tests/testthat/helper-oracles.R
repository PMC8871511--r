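# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (BFS by hand, polynomial roots via polyroot,
# naive map iteration) so tests compare two routes to the same quantity.

# Breadth-first shortest directed path lengths from `from` (0-based),
# NA when unreachable.
bfs_layers_oracle <- function(N, edges, from) {
  adj <- lapply(seq_len(N) - 1L, function(u) edges$target[edges$source == u])
  dist <- rep(NA_integer_, N)
  dist[from + 1L] <- 0L
  queue <- from
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u + 1L]]) {
      if (is.na(dist[v + 1L])) {
        dist[v + 1L] <- dist[u + 1L] + 1L
        queue <- c(queue, v)
      }
    }
  }
  dist
}

# Interior local minima of a polynomial (coeffs for powers 0..P) on an
# interval, via polyroot on the derivative plus a second-difference test.
poly_minima_oracle <- function(coeffs, interval, tol = 1e-7) {
  p <- length(coeffs) - 1
  dcf <- coeffs[-1] * seq_len(p)
  while (length(dcf) > 1 && abs(dcf[length(dcf)]) < 1e-14) {
    dcf <- dcf[-length(dcf)]
  }
  if (all(abs(dcf) < 1e-14)) return(numeric(0))
  rts <- polyroot(dcf)
  re <- Re(rts[abs(Im(rts)) < 1e-7])
  re <- sort(unique(round(re, 9)))
  re <- re[re > interval[1] + tol & re < interval[2] - tol]
  evalp <- function(y) {
    out <- rep(coeffs[length(coeffs)], length(y))
    for (i in rev(seq_len(length(coeffs) - 1))) out <- out * y + coeffs[i]
    out
  }
  h <- 1e-5 * diff(interval)
  re[evalp(re - h) > evalp(re) + 1e-12 & evalp(re + h) > evalp(re) + 1e-12]
}

# Scalar iteration of the elementary map, written independently.
scalar_iterate_oracle <- function(x0, a, b, n) {
  out <- numeric(n)
  x <- x0
  for (t in seq_len(n)) {
    x <- a[1] * tanh(a[2] * (x - a[3])) - a[4] * tanh(a[5] * (x - a[6])) + b
    out[t] <- x
  }
  out
}

# A tiny contracting test network: 4 units on a diamond with one
# feedback edge (3 -> 1).
diamond_net <- function(weight = 0.8) {
  eds_network(4,
              edges = data.frame(source = c(0, 0, 1, 2, 3),
                                 target = c(1, 2, 3, 3, 1),
                                 weight = weight),
              shared_params = elementary_params(a1 = 0.9, a2 = 1))
}
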