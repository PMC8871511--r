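#' Layer assignment by closeness to the receiver unit
#'
#' The layer of a unit is the least number of steps along directed
#' connected paths from the receiver (unit 0 by default), i.e. the
#' shortest directed path length in signal-propagation order. Units not
#' reachable from the receiver are assigned `NA` (unreachable).
#'
#' @param net an [eds_network()] (also accepts an [erc_network()] via its
#'   edge representation).
#' @return Integer vector of length `N` (layer per unit, 0-based unit
#'   order, `NA` = unreachable), class `layer_assignment`.
#' @export
assign_layers <- function(net) {
  N <- net$N
  g <- igraph::make_empty_graph(n = N, directed = TRUE)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$source + 1L,
                                    net$edges$target + 1L))
  }
  d <- igraph::distances(g, v = net$receiver + 1L, mode = "out")[1, ]
  layers <- rep(NA_integer_, N)
  layers[is.finite(d)] <- as.integer(d[is.finite(d)])
  structure(layers, names = paste0("x", seq_len(N) - 1L),
            class = "layer_assignment")
}

#' Classify edges as feedforward, feedback or lateral
#'
#' Given the layer assignment, an edge from a lower to a higher layer is
#' feedforward, from a higher to a lower layer is feedback, and between
#' equal layers is lateral. Edges touching an unreachable unit are
#' labelled `"unreachable"`.
#'
#' @param net an [eds_network()].
#' @param layers a [assign_layers()] result for `net`.
#' @return `net$edges` with an added factor column `class`.
#' @export
classify_edges <- function(net, layers = assign_layers(net)) {
  e <- net$edges
  ls <- unclass(layers)[e$source + 1L]
  lt <- unclass(layers)[e$target + 1L]
  lab <- rep("unreachable", nrow(e))
  ok <- !is.na(ls) & !is.na(lt)
  lab[ok & ls < lt] <- "feedforward"
  lab[ok & ls > lt] <- "feedback"
  lab[ok & ls == lt] <- "lateral"
  e$class <- factor(lab, levels = c("feedforward", "feedback", "lateral",
                                    "unreachable"))
  e
}

#' Remove a set of edges from a network
#'
#' Returns a copy of the network with exactly the listed edges removed;
#' everything else (parameters, biases, receiver) is untouched.
#'
#' @param net an [eds_network()].
#' @param edges data frame with columns `source` and `target` (0-based)
#'   identifying edges present in `net`.
#' @return The ablated [eds_network()].
#' @export
ablate <- function(net, edges) {
  if (NROW(edges) == 0) return(net)
  key <- function(s, t) paste(s, t, sep = "->")
  have <- key(net$edges$source, net$edges$target)
  want <- key(edges$source, edges$target)
  missing <- setdiff(want, have)
  if (length(missing) > 0) {
    stop("ablate: edges not present in network: ",
         paste(missing, collapse = ", "))
  }
  net$edges <- net$edges[!(have %in% want), , drop = FALSE]
  rownames(net$edges) <- NULL
  net
}

#' Protocol for pattern-driven ensemble ablation runs
#'
#' @param patterns number of input pattern identities `P`; identity `p`
#'   is encoded as the constant input level `-1 + 2 p / (P - 1)`.
#' @param T_in steps during which the input is presented.
#' @param T_steps total simulated steps.
#' @param E ensemble size (trials).
#' @param bins mutual-information histogram bins.
#' @param seed seed shared by every variant (so differences between
#'   variants reflect structure only).
#' @return An object of class `ablation_protocol`.
#' @export
ablation_protocol <- function(patterns = 4, T_in = 20, T_steps = 100,
                              E = 200, bins = 8, seed = 1L) {
  stopifnot(patterns >= 2, T_in < T_steps, E >= 2)
  structure(list(patterns = as.integer(patterns), T_in = as.integer(T_in),
                 T_steps = as.integer(T_steps), E = as.integer(E),
                 bins = as.integer(bins), seed = as.integer(seed)),
            class = "ablation_protocol")
}

#' Feedback-ablation experiment with time-dependent mutual information
#'
#' For each named variant (an edge set to remove, or the keywords
#' `"none"` and `"all_feedback"`), simulates an ensemble of trials in
#' which a random pattern identity drives the receiver during the
#' presentation window and is switched off afterwards, then measures the
#' time-dependent mutual information between the probe unit and the
#' pattern identity, its log-linear decay rate over the post-offset
#' window, and its time-averaged value there. All variants share the
#' same seeds, so differences reflect network structure only. Unit
#' states are binned over the fixed dynamical range of the network
#' ([eds_state_bound()]), so the series measures information at a fixed
#' state resolution: trajectories that converge below one bin width
#' lose measured information rather than being rescaled with the
#' shrinking observed range.
#'
#' @param net an [eds_network()].
#' @param probe 0-based probe unit index.
#' @param variants named list; each element is an edge data frame
#'   (`source`, `target`) or one of the keywords `"none"`,
#'   `"all_feedback"`.
#' @param protocol an [ablation_protocol()].
#' @return Named list of reports, one per variant: `variant`, `mi`
#'   (`mi_series`), `decay_rate`, `mean_mi`, `removed` (edge count),
#'   `probe_unreachable` flag; attribute `protocol` carries the settings.
#' @export
ablation_experiment <- function(net, probe, variants,
                                protocol = ablation_protocol()) {
  stopifnot(inherits(net, "eds_network"), probe >= 0, probe < net$N,
            length(names(variants)) == length(variants))
  pr <- protocol
  set.seed(pr$seed)
  labels <- sample.int(pr$patterns, pr$E, replace = TRUE) - 1L
  reports <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    rmv <- if (identical(v, "none")) {
      empty_edges()
    } else if (identical(v, "all_feedback")) {
      ec <- classify_edges(net)
      ec[ec$class == "feedback", c("source", "target"), drop = FALSE]
    } else {
      as.data.frame(v)
    }
    nv <- ablate(net, rmv)
    unreachable <- is.na(unclass(assign_layers(nv))[probe + 1L])
    if (unreachable) {
      warning("ablation_experiment: probe unit ", probe,
              " unreachable in variant '", nm, "'")
    }
    tr <- simulate_eds_ensemble(nv, labels, pr$patterns, pr$T_in,
                                pr$T_steps, seed = pr$seed)
    ens <- ensemble_trace(tr, labels = labels)
    B <- eds_state_bound(net)
    mi <- time_mi(ens, probe, ref = "labels", bins = pr$bins,
                  state_range = c(-B, B))
    win <- c(pr$T_in, pr$T_steps)
    sel <- mi$t >= win[1] & mi$t <= win[2]
    list(variant = nm,
         mi = mi,
         decay_rate = as.numeric(decay_rate(mi, window = win)),
         mean_mi = mean(mi$bits[sel]),
         removed = nrow(rmv),
         probe_unreachable = unreachable)
  })
  names(reports) <- names(variants)
  attr(reports, "protocol") <- pr
  reports
}
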