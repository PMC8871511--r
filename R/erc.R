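#' Leaky-tanh reservoir network with a two-layer internal partition
#'
#' The reservoir update for unit `k` is
#' \deqn{x_k(t+1) = (1-\alpha_k) x_k(t) + \alpha_k \tanh(\sum_l w_{kl}
#'   x_l(t) + w_{k0} + \sum_l w^{(in)}_{kl} I_l(t)) + \sigma_k(t),}
#' with per-unit leak rates, a bias, input weights and i.i.d. Gaussian
#' noise. Units are partitioned into an internal input layer (the first
#' `n_input` units, the only ones receiving external input) and an
#' internal output layer (the rest, the only ones feeding the linear
#' readout). Edges from the output layer back into the input layer are
#' the feedback class probed by [feedback_scale_sweep()].
#'
#' @param N number of units.
#' @param W `N x N` internal weight matrix, `W[k, l]` the weight of the
#'   connection `l -> k`; the diagonal is forced to zero.
#' @param W_in `N x C` input weight matrix; rows outside the input layer
#'   are forced to zero.
#' @param bias length-`N` bias vector (`w_k0`).
#' @param leak per-unit leak rates in (0, 1] (scalar recycled).
#' @param noise_std standard deviation of the state noise.
#' @param n_input size of the internal input layer (default `N / 2`).
#' @return An object of class `erc_network`. The element `edges` exposes
#'   the non-zero weights as a 0-based edge data frame, and `receiver`
#'   is 0 so the layer tools apply unchanged.
#' @export
erc_network <- function(N, W, W_in, bias = rep(0, N), leak = 0.5,
                        noise_std = 1e-3, n_input = N %/% 2) {
  stopifnot(nrow(W) == N, ncol(W) == N, nrow(W_in) == N,
            all(is.finite(W)), all(is.finite(W_in)),
            length(bias) == N, n_input >= 1, n_input < N)
  leak <- rep(leak, length.out = N)
  if (any(leak <= 0 | leak > 1)) stop("erc_network: leak rates must lie in (0, 1]")
  if (noise_std < 0) stop("erc_network: noise_std must be >= 0")
  diag(W) <- 0
  if (n_input < N) W_in[(n_input + 1):N, ] <- 0
  nz <- which(W != 0, arr.ind = TRUE)
  edges <- data.frame(source = nz[, 2] - 1L, target = nz[, 1] - 1L,
                      weight = W[nz])
  structure(list(N = as.integer(N), W = W, W_in = W_in,
                 bias = as.numeric(bias), leak = leak,
                 noise_std = noise_std, n_input = as.integer(n_input),
                 input_units = seq_len(n_input) - 1L,
                 output_units = seq.int(n_input, N - 1L),
                 edges = edges, receiver = 0L),
            class = "erc_network")
}

#' @export
print.erc_network <- function(x, ...) {
  cat("erc_network:", x$N, "units (", x$n_input, "input-layer /",
      x$N - x$n_input, "output-layer ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' One reservoir update step
#'
#' @param x length-`N` state vector.
#' @param net an [erc_network()].
#' @param input_row length-`C` input vector for this step (`NULL` for no
#'   input). Noise is drawn from the current RNG state when
#'   `net$noise_std > 0`.
#' @return The next state vector.
#' @export
reservoir_step <- function(x, net, input_row = NULL) {
  stopifnot(length(x) == net$N)
  pre <- drop(net$W %*% x) + net$bias
  if (!is.null(input_row)) {
    if (length(input_row) != ncol(net$W_in)) {
      stop("reservoir_step: input dimension mismatch")
    }
    pre <- pre + drop(net$W_in %*% input_row)
  }
  xn <- (1 - net$leak) * x + net$leak * tanh(pre)
  if (net$noise_std > 0) xn <- xn + stats::rnorm(net$N, 0, net$noise_std)
  xn
}

#' Run a single trial through the reservoir
#'
#' Starts from the zero state and applies [reservoir_step()] for every
#' input row, recording the post-washout states.
#'
#' @param net an [erc_network()].
#' @param input `T x C` input matrix.
#' @param washout leading steps discarded.
#' @return `(T - washout) x N` state matrix.
#' @export
run_trial <- function(net, input, washout = 10) {
  T_steps <- nrow(input)
  stopifnot(washout < T_steps)
  x <- numeric(net$N)
  out <- matrix(0, T_steps - washout, net$N)
  for (t in seq_len(T_steps)) {
    x <- reservoir_step(x, net, input[t, ])
    if (t > washout) out[t - washout, ] <- x
  }
  out
}

# Batched trial runner: inputs is a T x C x E array; returns an
# E x N x window array of the last `window` post-washout states.
run_erc_trials <- function(net, inputs, washout = 10, window = 30,
                           seed = NULL) {
  d <- dim(inputs)
  T_steps <- d[1]; C <- d[2]; E <- d[3]
  stopifnot(washout + window <= T_steps, ncol(net$W_in) == C)
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(0, E, net$N)
  Wt <- t(net$W)
  Wint <- t(net$W_in)
  alpha <- matrix(net$leak, E, net$N, byrow = TRUE)
  bmat <- matrix(net$bias, E, net$N, byrow = TRUE)
  rec <- array(0, dim = c(E, net$N, window))
  first_rec <- T_steps - window + 1L
  for (t in seq_len(T_steps)) {
    pre <- X %*% Wt + matrix(inputs[t, , ], E, C, byrow = TRUE) %*% Wint + bmat
    X <- (1 - alpha) * X + alpha * tanh(pre)
    if (net$noise_std > 0) {
      X <- X + matrix(stats::rnorm(E * net$N, 0, net$noise_std), E, net$N)
    }
    if (t >= first_rec) rec[, , t - first_rec + 1L] <- X
  }
  rec
}

#' Ridge-regression readout training
#'
#' Solves `min ||S W - Y||^2 + ridge ||W||^2` in closed form via the
#' normal equations. With `ridge = 0` and rank-deficient `S` the
#' minimum-norm least-squares solution (SVD pseudoinverse) is returned.
#'
#' @param states `R x F` matrix of reservoir states (rows = samples).
#' @param targets `R x K` target matrix.
#' @param ridge regularisation strength (>= 0).
#' @return `F x K` readout weight matrix.
#' @export
train_readout <- function(states, targets, ridge = 1e-4) {
  stopifnot(nrow(states) == nrow(targets), ridge >= 0)
  targets <- as.matrix(targets)
  if (ridge > 0) {
    A <- crossprod(states) + diag(ridge, ncol(states))
    return(solve(A, crossprod(states, targets)))
  }
  sv <- svd(states)
  pos <- sv$d > max(dim(states)) * .Machine$double.eps * max(sv$d, 0)
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, targets))
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, length(labels), length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

# Stack the response-window states of the output-layer units for a set
# of trials: rows ordered trial-major, one row per (trial, window step).
stack_output_states <- function(rec, net, trials) {
  out_cols <- net$output_units + 1L
  window <- dim(rec)[3]
  blocks <- lapply(trials, function(e) t(rec[e, out_cols, ]))
  do.call(rbind, blocks)
}

#' Train per-modality readouts and evaluate classification accuracy
#'
#' Runs every trial through the reservoir once, trains one ridge readout
#' per modality on the training split (one-hot targets over that
#' modality's classes, one row per response-window step), and scores the
#' evaluation split: a trial's outputs are averaged over the response
#' window and the predicted class is the argmax within the trial's
#' modality group (ties broken by the lowest class index).
#'
#' @param net an [erc_network()].
#' @param tasks a [make_patterns()] task set.
#' @param ridge ridge strength for [train_readout()].
#' @param washout,window washout length and response-window length.
#' @param seed seed for the reservoir noise (fixing it makes the
#'   evaluation a deterministic function of the network).
#' @param eval_set which split to score (`"val"` or `"train"`).
#' @return List of class `accuracy_report`: `accuracy` (named percent
#'   per modality), `mean_accuracy`, `readouts`, `confusion` (per
#'   modality), `n_trials`.
#' @export
erc_fit_eval <- function(net, tasks, ridge = 1e-4, washout = 10,
                         window = 30, seed = 1L, eval_set = "val") {
  info <- tasks$info
  rec <- run_erc_trials(net, tasks$inputs, washout, window, seed)
  modalities <- unique(info$modality)
  readouts <- list()
  accuracy <- c()
  confusion <- list()
  for (m in modalities) {
    classes <- sort(unique(info$class[info$modality == m]))
    tr <- which(info$modality == m & info$set == "train")
    ev <- which(info$modality == m & info$set == eval_set)
    if (length(tr) == 0 || length(ev) == 0) next
    S <- stack_output_states(rec, net, tr)
    Y <- one_hot(rep(info$class[tr], each = dim(rec)[3]), classes)
    Wr <- train_readout(S, Y, ridge)
    pred <- vapply(ev, function(e) {
      scores <- colMeans(t(rec[e, net$output_units + 1L, ]) %*% Wr)
      classes[which.max(scores)]
    }, numeric(1))
    accuracy[m] <- 100 * mean(pred == info$class[ev])
    confusion[[m]] <- table(truth = info$class[ev], predicted = pred)
    readouts[[m]] <- Wr
  }
  structure(list(accuracy = accuracy,
                 mean_accuracy = mean(accuracy),
                 readouts = readouts, confusion = confusion,
                 n_trials = nrow(info)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report: mean", round(x$mean_accuracy, 2), "% (",
      paste(names(x$accuracy), round(x$accuracy, 2), sep = " = ",
            collapse = " %, "), "% )\n")
  invisible(x)
}

#' Evolve the internal wiring of a reservoir computer
#'
#' The gene is the flattened vector of off-diagonal internal weights
#' (zero entries are absent edges); fitness is the mean validation
#' accuracy across modalities after ridge readout training, evaluated
#' with a fixed noise seed so fitness is a pure function of the gene.
#' Input weights, biases and leak rates stay fixed during evolution.
#'
#' @param template an [erc_network()] providing sizes, `W_in`, bias,
#'   leak, noise and partition; its `W` seeds nothing.
#' @param tasks a [make_patterns()] task set.
#' @param ga a [ga_config()].
#' @param ridge,washout,window evaluation settings, see [erc_fit_eval()].
#' @param p_init edge probability of the random initial genomes.
#' @param weight_scale weight standard deviation of the initial genomes.
#' @param weight_bound box bound on evolved weights.
#' @return List: `result` (an [evolve()] result), `initial_net` and
#'   `final_net` snapshots (the best initial genome and the best final
#'   genome as networks), `fitness_fn`.
#' @export
evolve_erc <- function(template, tasks, ga = ga_config(),
                       ridge = 1e-4, washout = 10, window = 30,
                       p_init = 0.1, weight_scale = 0.1,
                       weight_bound = 1) {
  N <- template$N
  n_loci <- N * N - N
  off <- which(diag(N) == 0)  # column-major off-diagonal positions
  layout <- c(weights = n_loci)
  bounds <- list(weights = c(-weight_bound, weight_bound))
  eval_seed <- ga$seed + 104729L  # fixed noise stream, independent of GA draws

  gene_to_net <- function(g) {
    W <- matrix(0, N, N)
    W[off] <- g$values
    erc_network(N, W, template$W_in, template$bias, template$leak,
                template$noise_std, template$n_input)
  }
  fitness <- function(g) {
    erc_fit_eval(gene_to_net(g), tasks, ridge, washout, window,
                 seed = eval_seed)$mean_accuracy
  }
  make_init <- function(i) {
    mask <- stats::runif(n_loci) < p_init
    v <- ifelse(mask, stats::rnorm(n_loci, 0, weight_scale), 0)
    gene(pmin(pmax(v, -weight_bound), weight_bound), layout, bounds)
  }
  set.seed(ga$seed)
  init <- lapply(seq_len(ga$population), function(i) make_init(i))
  init_fits <- vapply(init, fitness, numeric(1))
  initial_net <- gene_to_net(init[[which.max(init_fits)]])
  res <- evolve(init, fitness, ga)
  list(result = res,
       initial_net = initial_net,
       final_net = gene_to_net(res$best_gene),
       initial_best_fitness = max(init_fits),
       fitness_fn = fitness)
}

#' Feedback scale-factor sweep
#'
#' Multiplies all feedback weights (internal output layer back to the
#' internal input layer) by each scale factor `s`, retrains the ridge
#' readouts, and reports the per-modality accuracy relative to the
#' unscaled network: `100 * accuracy(s) / accuracy(s = 1)`. `s = 0` is
#' full feedback ablation.
#'
#' @param net an evolved [erc_network()].
#' @param s_grid numeric vector of non-negative scale factors.
#' @param tasks,ridge,washout,window,seed see [erc_fit_eval()].
#' @return Data frame with columns `s`, one `rel_<modality>` column per
#'   modality (percent of the `s = 1` accuracy), and absolute accuracy
#'   columns `acc_<modality>`.
#' @export
feedback_scale_sweep <- function(net, s_grid, tasks, ridge = 1e-4,
                                 washout = 10, window = 30, seed = 1L) {
  stopifnot(length(s_grid) >= 1, all(s_grid >= 0))
  fb_rows <- net$input_units + 1L
  fb_cols <- net$output_units + 1L
  eval_s <- function(s) {
    W <- net$W
    W[fb_rows, fb_cols] <- s * W[fb_rows, fb_cols]
    nv <- erc_network(net$N, W, net$W_in, net$bias, net$leak,
                      net$noise_std, net$n_input)
    erc_fit_eval(nv, tasks, ridge, washout, window, seed)$accuracy
  }
  ref <- eval_s(1)
  rows <- lapply(s_grid, function(s) {
    acc <- eval_s(s)
    rel <- 100 * acc / ref
    stats::setNames(c(s, rel, acc),
                    c("s", paste0("rel_", names(acc)), paste0("acc_", names(acc))))
  })
  as.data.frame(do.call(rbind, rows))
}

#' Evolved-reservoir feedback scale-factor study
#'
#' The reservoir counterpart of the heterarchy analysis in one call:
#' build the spatial/temporal task set, evolve the internal wiring of a
#' reservoir from random initial genomes, then scale all feedback
#' weights by each factor in `s_grid` (retraining the ridge readouts
#' each time) and report the accuracy relative to the unscaled evolved
#' network, together with structure statistics of the initial and final
#' networks.
#'
#' @param seed master seed; task, template, GA and sweep streams are
#'   derived from it.
#' @param N reservoir size.
#' @param ga a [ga_config()] (its seed is overridden).
#' @param s_grid feedback scale factors.
#' @param trials_per_class trials per class of the task generator.
#' @return List: `sweep` (the [feedback_scale_sweep()] data frame),
#'   `evolution` (the [evolve_erc()] output), `structure_initial`,
#'   `structure_final`.
#' @export
erc_experiment <- function(seed, N = 60,
                           ga = ga_config(population = 16,
                                          generations = 30),
                           s_grid = c(0, 0.5, 1, 1.5, 2),
                           trials_per_class = 20) {
  tasks <- make_patterns(trials_per_class = trials_per_class,
                         seed = child_seed(seed, "tasks"))
  tmpl <- random_network(N, p = 0, seed = child_seed(seed, "template"),
                         kind = "erc")
  ga$seed <- child_seed(seed, "ga")
  ev <- evolve_erc(tmpl, tasks, ga)
  sw <- feedback_scale_sweep(ev$final_net, s_grid, tasks,
                             seed = child_seed(seed, "sweep"))
  list(sweep = sw, evolution = ev,
       structure_initial = structure_stats(ev$initial_net),
       structure_final = structure_stats(ev$final_net))
}

#' Structure statistics of a partitioned reservoir
#'
#' Counts edges and sums absolute weights by class with respect to the
#' internal partition: feedforward (input layer to output layer),
#' feedback (output layer to input layer), within-input and
#' within-output. Connectivity cost is the total edge count and total
#' absolute weight. Weights with magnitude below `threshold` count as
#' absent edges.
#'
#' @param net an [erc_network()].
#' @param threshold absence threshold on `|weight|`.
#' @return Data frame with one row per edge class plus a `total` row;
#'   columns `class`, `count`, `weight_sum`.
#' @export
structure_stats <- function(net, threshold = 1e-3) {
  W <- net$W
  W[abs(W) < threshold] <- 0
  inp <- net$input_units + 1L
  out <- net$output_units + 1L
  block <- function(rows, cols) {
    B <- W[rows, cols, drop = FALSE]
    c(count = sum(B != 0), weight_sum = sum(abs(B)))
  }
  m <- rbind(feedforward = block(out, inp),   # input layer -> output layer
             feedback = block(inp, out),      # output layer -> input layer
             within_input = block(inp, inp),
             within_output = block(out, out))
  df <- data.frame(class = rownames(m), count = m[, "count"],
                   weight_sum = m[, "weight_sum"], row.names = NULL)
  rbind(df, data.frame(class = "total", count = sum(df$count),
                       weight_sum = sum(df$weight_sum)))
}

#' Write / read a reservoir network (TSV edge list + JSON sidecar)
#'
#' @param net an [erc_network()].
#' @param tsv edge-list path (`source<TAB>target<TAB>weight`, 0-based).
#' @param json sidecar path storing `N`, `n_input`, `W_in`, `bias`,
#'   `leak`, `noise_std`.
#' @export
write_erc_network <- function(net, tsv, json = paste0(tsv, ".json")) {
  utils::write.table(net$edges, tsv, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  side <- list(N = net$N, n_input = net$n_input,
               channels = ncol(net$W_in),
               W_in = as.vector(net$W_in), bias = net$bias,
               leak = net$leak, noise_std = net$noise_std)
  jsonlite::write_json(side, json, auto_unbox = TRUE, digits = NA)
  invisible(net)
}

#' @rdname write_erc_network
#' @export
read_erc_network <- function(tsv, json = paste0(tsv, ".json")) {
  side <- jsonlite::read_json(json, simplifyVector = TRUE)
  N <- side$N
  W <- matrix(0, N, N)
  if (file.size(tsv) > 0) {
    e <- utils::read.table(tsv, sep = "\t",
                           col.names = c("source", "target", "weight"))
    W[cbind(e$target + 1L, e$source + 1L)] <- e$weight
  }
  W_in <- matrix(side$W_in, nrow = N, ncol = side$channels)
  erc_network(N, W, W_in, side$bias, side$leak, side$noise_std,
              side$n_input)
}
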