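#' Network of coupled elementary map units
#'
#' A directed, weighted network whose nodes are elementary two-tanh map
#' units sharing the amplitude/gain/threshold parameters `a1..a6` but
#' carrying individual biases `b_k`. Unit indices are 0-based throughout
#' (unit 0 is, by default, the receiver of the external input), matching
#' the edge-list file format.
#'
#' Coupling and external input enter the map argument: with
#' `u_k = x_k + sum_l w_kl x_l + input_gain * [k == receiver] * I(t)`,
#' the update is `x_k(t+1) = a1 tanh(a2 (u_k - a3)) - a4 tanh(a5 (u_k -
#' a6)) + b_k`, which preserves the `|a1| + |a4| + |b_k|` state bound of
#' the isolated unit exactly.
#'
#' @param N number of units.
#' @param edges data frame with columns `source`, `target`, `weight`
#'   (0-based unit indices, no self-edges).
#' @param shared_params an [elementary_params()] object; its `b` field is
#'   ignored in favour of `biases`.
#' @param biases length-`N` numeric vector of per-unit biases.
#' @param receiver 0-based index of the unit receiving external input.
#' @param input_gain multiplier applied to the external signal.
#' @return An object of class `eds_network`.
#' @export
eds_network <- function(N, edges = empty_edges(), shared_params = elementary_params(),
                        biases = rep(0, N), receiver = 0L, input_gain = 1) {
  stopifnot(N >= 1, length(biases) == N, all(is.finite(biases)),
            inherits(shared_params, "elementary_params"))
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("source", "target", "weight") %in% names(edges)))
    if (!all(is.finite(edges$weight))) stop("eds_network: weights must be finite")
    if (any(edges$source < 0 | edges$source >= N |
            edges$target < 0 | edges$target >= N)) {
      stop("eds_network: edge indices out of range [0, N)")
    }
    if (any(edges$source == edges$target)) {
      stop("eds_network: self-edges are not allowed (self-dependence is intrinsic to the unit map)")
    }
    if (anyDuplicated(edges[, c("source", "target")])) {
      stop("eds_network: duplicate edges")
    }
  }
  if (receiver < 0 || receiver >= N) stop("eds_network: receiver out of range")
  structure(list(N = as.integer(N),
                 edges = edges[, c("source", "target", "weight")],
                 shared_params = shared_params,
                 biases = as.numeric(biases),
                 receiver = as.integer(receiver),
                 input_gain = input_gain),
            class = "eds_network")
}

#' @export
empty_edges <- function() {
  data.frame(source = integer(0), target = integer(0), weight = numeric(0))
}

#' @export
print.eds_network <- function(x, ...) {
  cat("eds_network:", x$N, "units,", nrow(x$edges),
      "edges, receiver = unit", x$receiver, "\n")
  invisible(x)
}

#' Dense coupling matrix of an EDS network
#'
#' @param net an [eds_network()].
#' @return `N x N` matrix `W` with `W[k+1, l+1]` the weight of edge
#'   `l -> k`, so that `W %*% x` sums incoming contributions per target.
#' @export
eds_adjacency <- function(net) {
  W <- matrix(0, net$N, net$N)
  if (nrow(net$edges) > 0) {
    W[cbind(net$edges$target + 1L, net$edges$source + 1L)] <- net$edges$weight
  }
  W
}

#' Simulate a coupled EDS network
#'
#' Iterates the coupled two-tanh map for `T` steps. Row `t` of the
#' returned trace is the state after `t` updates; external input value
#' `input[t]` is applied during the update that produces row `t`.
#'
#' @param net an [eds_network()].
#' @param input optional numeric external signal of length at least
#'   `T_steps` (injected at the receiver unit); `NULL` for no input.
#' @param T_steps number of update steps.
#' @param x0 initial state vector (length `N`); when `NULL`, drawn
#'   independently uniform on \[-0.1, 0.1\] from `seed`.
#' @param seed RNG seed used only when `x0` is `NULL`.
#' @return A `T_steps x N` matrix of class `state_trace` (column names
#'   `x0..x{N-1}`, attribute `t0 = 1`).
#' @export
simulate_network <- function(net, input = NULL, T_steps, x0 = NULL, seed = NULL) {
  stopifnot(inherits(net, "eds_network"), T_steps >= 1)
  if (!is.null(input) && length(input) < T_steps) {
    stop("simulate_network: input shorter than T_steps")
  }
  if (is.null(x0)) {
    if (!is.null(seed)) set.seed(seed)
    x0 <- stats::runif(net$N, -0.1, 0.1)
  }
  stopifnot(length(x0) == net$N, all(is.finite(x0)))
  W <- eds_adjacency(net)
  p <- net$shared_params
  b <- net$biases
  rx <- net$receiver + 1L
  out <- matrix(0, T_steps, net$N)
  x <- as.numeric(x0)
  for (t in seq_len(T_steps)) {
    u <- x + drop(W %*% x)
    if (!is.null(input)) u[rx] <- u[rx] + net$input_gain * input[t]
    x <- p$a1 * tanh(p$a2 * (u - p$a3)) - p$a4 * tanh(p$a5 * (u - p$a6)) + b
    out[t, ] <- x
  }
  colnames(out) <- paste0("x", seq_len(net$N) - 1L)
  structure(out, t0 = 1L, class = c("state_trace", class(out)))
}

#' Simulate an ensemble of trials with pattern-coded constant input
#'
#' Each trial presents one of `P` constant input levels (the pattern
#' identity mapped linearly onto \[-1, 1\]) at the receiver during
#' `t = 1..T_in`, with the input off afterwards. All trials share the
#' network; initial conditions are drawn independently per trial.
#'
#' @param net an [eds_network()].
#' @param labels integer vector (length `E`) of pattern identities in
#'   `0..P-1`.
#' @param P number of patterns.
#' @param T_in input presentation length (steps).
#' @param T_steps total simulated steps.
#' @param seed RNG seed for the initial conditions.
#' @param pattern_signals optional `T_in x P` matrix of per-pattern
#'   input sequences; column `p + 1` drives trials of pattern `p`
#'   during the presentation window. Default (`NULL`): each pattern is
#'   a constant level on \[-1, 1\].
#' @return An `E x T_steps x N` array of trial traces.
#' @export
simulate_eds_ensemble <- function(net, labels, P, T_in, T_steps, seed = 1L,
                                  pattern_signals = NULL) {
  stopifnot(inherits(net, "eds_network"), T_in <= T_steps, P >= 1)
  E <- length(labels)
  stopifnot(E >= 2, all(labels >= 0 & labels < P))
  if (!is.null(pattern_signals)) {
    stopifnot(nrow(pattern_signals) >= T_in, ncol(pattern_signals) == P)
  }
  levels <- if (P == 1) 0 else -1 + 2 * labels / (P - 1)
  set.seed(seed)
  X <- matrix(stats::runif(E * net$N, -0.1, 0.1), E, net$N)
  W <- eds_adjacency(net)
  p <- net$shared_params
  bmat <- matrix(net$biases, E, net$N, byrow = TRUE)
  rx <- net$receiver + 1L
  out <- array(0, dim = c(E, T_steps, net$N))
  for (t in seq_len(T_steps)) {
    U <- X + X %*% t(W)
    if (t <= T_in) {
      drive <- if (is.null(pattern_signals)) levels
               else pattern_signals[t, labels + 1L]
      U[, rx] <- U[, rx] + net$input_gain * drive
    }
    X <- p$a1 * tanh(p$a2 * (U - p$a3)) - p$a4 * tanh(p$a5 * (U - p$a6)) + bmat
    out[, t, ] <- X
  }
  out
}

#' Write / read an EDS network (TSV edge list + JSON sidecar)
#'
#' The edge list is a headerless three-column TSV
#' `source<TAB>target<TAB>weight` with 0-based unit indices; the sidecar
#' JSON stores `N`, `shared_params`, `biases`, `receiver`, `input_gain`.
#'
#' @param net an [eds_network()].
#' @param tsv path of the edge-list file.
#' @param json path of the JSON sidecar; defaults to `tsv` with a
#'   `.json` extension appended.
#' @return `write_eds_network` returns `net` invisibly;
#'   `read_eds_network` returns an [eds_network()].
#' @export
write_eds_network <- function(net, tsv, json = paste0(tsv, ".json")) {
  stopifnot(inherits(net, "eds_network"))
  utils::write.table(net$edges, tsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  side <- list(N = net$N,
               shared_params = unclass(net$shared_params),
               biases = net$biases,
               receiver = net$receiver,
               input_gain = net$input_gain)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(net)
}

#' @rdname write_eds_network
#' @export
read_eds_network <- function(tsv, json = paste0(tsv, ".json")) {
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  edges <- if (file.size(tsv) > 0) {
    utils::read.table(tsv, sep = "\t",
                      col.names = c("source", "target", "weight"))
  } else empty_edges()
  sp <- do.call(elementary_params, as.list(side$shared_params))
  eds_network(N = side$N, edges = edges, shared_params = sp,
              biases = side$biases, receiver = side$receiver,
              input_gain = side$input_gain)
}

#' Write / read a state trace as CSV
#'
#' One row per time step, header `t,x0,...,x{N-1}`.
#'
#' @param trace a `state_trace` matrix.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  t0 <- attr(trace, "t0") %||% 1L
  df <- data.frame(t = seq_len(nrow(trace)) + t0 - 1L, unclass(trace))
  names(df) <- c("t", colnames(trace))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(trace)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  structure(m, t0 = as.integer(df$t[1]), class = c("state_trace", class(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' State bound of an EDS network
#'
#' Every simulated state satisfies `|x_k(t)| <= |a1| + |a4| + |b_k|` for
#' `t >= 1`; this returns the network-wide bound
#' `|a1| + |a4| + max|b_k|`, used e.g. as the fixed binning range of the
#' mutual-information protocol.
#'
#' @param net an [eds_network()].
#' @return Positive scalar bound.
#' @export
eds_state_bound <- function(net) {
  abs(net$shared_params$a1) + abs(net$shared_params$a4) +
    max(abs(net$biases))
}
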