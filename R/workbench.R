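#' Synthetic external input signals
#'
#' @param kind `"binary"` (i.i.d. plus/minus one), `"sine"`
#'   (`amplitude * sin(2 pi (t - 1) / period + phase)`), or
#'   `"logistic"` (the chaotic orbit of `4 x (1 - x)` from a seeded
#'   start in (0, 1)).
#' @param T_steps signal length (>= 1).
#' @param params list of kind-specific settings: `period`, `amplitude`,
#'   `phase` for `"sine"`.
#' @param seed RNG seed (binary draws; logistic initial condition).
#' @return Numeric vector of length `T_steps` (class `signal_trace`).
#' @export
make_input_signal <- function(kind = c("binary", "sine", "logistic"),
                              T_steps, params = list(), seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(T_steps >= 1)
  set.seed(seed)
  v <- switch(kind,
    binary = sample(c(-1, 1), T_steps, replace = TRUE),
    sine = {
      period <- params$period %||% 8
      amplitude <- params$amplitude %||% 1
      phase <- params$phase %||% 0
      amplitude * sin(2 * pi * (seq_len(T_steps) - 1) / period + phase)
    },
    logistic = {
      x <- stats::runif(1, 0.1, 0.9)
      out <- numeric(T_steps)
      for (t in seq_len(T_steps)) {
        out[t] <- x
        x <- 4 * x * (1 - x)
      }
      out
    })
  structure(v, kind = kind, class = c("signal_trace", class(v)))
}

#' Spatial / temporal classification task set
#'
#' Builds balanced trials of two modalities on shared input channels:
#' spatial classes are fixed random plus/minus-one channel vectors held
#' constant over the trial (a static "visual" pattern), temporal classes
#' are sinusoids of class-specific periods applied to all channels with
#' a random phase per trial (a time-coded "auditory" pattern). Trials
#' are split into train and validation sets by stratified seeded
#' shuffling.
#'
#' @param n_spatial,n_temporal number of classes per modality.
#' @param trials_per_class trials generated for every class.
#' @param T_steps trial length.
#' @param channels number of input channels.
#' @param periods temporal class periods (length `n_temporal`).
#' @param train_frac fraction of trials per class assigned to training.
#' @param seed RNG seed.
#' @return An object of class `task_set`: `inputs` (`T x channels x E`
#'   array), `info` (data frame `modality`, `class`, `set`), and the
#'   generating settings.
#' @export
make_patterns <- function(n_spatial = 4, n_temporal = 4,
                          trials_per_class = 20, T_steps = 60,
                          channels = 8, periods = c(4, 8, 16, 32),
                          train_frac = 0.7, seed = 1L) {
  stopifnot(n_spatial >= 1 || n_temporal >= 1, trials_per_class >= 1,
            length(periods) >= n_temporal)
  set.seed(seed)
  protos <- matrix(sample(c(-1, 1), n_spatial * channels, replace = TRUE),
                   n_spatial, channels)
  E <- (n_spatial + n_temporal) * trials_per_class
  inputs <- array(0, dim = c(T_steps, channels, E))
  info <- data.frame(modality = character(E), class = integer(E),
                     set = character(E))
  e <- 0L
  for (cl in seq_len(n_spatial)) {
    for (r in seq_len(trials_per_class)) {
      e <- e + 1L
      inputs[, , e] <- matrix(protos[cl, ], T_steps, channels, byrow = TRUE)
      info$modality[e] <- "spatial"; info$class[e] <- cl
    }
  }
  for (cl in seq_len(n_temporal)) {
    for (r in seq_len(trials_per_class)) {
      e <- e + 1L
      phase <- stats::runif(1, 0, 2 * pi)
      wave <- sin(2 * pi * (seq_len(T_steps) - 1) / periods[cl] + phase)
      inputs[, , e] <- matrix(wave, T_steps, channels)
      info$modality[e] <- "temporal"; info$class[e] <- cl
    }
  }
  info$set <- "val"
  n_train <- round(train_frac * trials_per_class)
  for (m in unique(info$modality)) {
    for (cl in unique(info$class[info$modality == m])) {
      idx <- which(info$modality == m & info$class == cl)
      info$set[sample(idx, n_train)] <- "train"
    }
  }
  structure(list(inputs = inputs, info = info,
                 n_spatial = n_spatial, n_temporal = n_temporal,
                 channels = channels, T_steps = T_steps,
                 periods = periods[seq_len(n_temporal)], seed = seed),
            class = "task_set")
}

#' @export
print.task_set <- function(x, ...) {
  cat("task_set:", dim(x$inputs)[3], "trials (", x$n_spatial,
      "spatial +", x$n_temporal, "temporal classes ),", x$T_steps,
      "steps x", x$channels, "channels\n")
  invisible(x)
}

#' Random directed network generators
#'
#' Each ordered non-self pair of units carries an edge with probability
#' `p`, with weight drawn from `Normal(0, weight_scale)`.
#'
#' @param N number of units.
#' @param p edge probability in `[0, 1]`.
#' @param weight_scale weight standard deviation.
#' @param seed RNG seed.
#' @param kind `"eds"` for an [eds_network()] of map units, `"erc"` for
#'   an [erc_network()] reservoir.
#' @param ... forwarded to the network constructor (`shared_params`,
#'   `biases`, ... for `"eds"`; `channels`, `leak`, `noise_std`,
#'   `input_scale`, ... for `"erc"`).
#' @return An [eds_network()] or [erc_network()].
#' @export
random_network <- function(N, p, weight_scale = 0.5, seed = 1L,
                           kind = c("eds", "erc"), ...) {
  kind <- match.arg(kind)
  stopifnot(p >= 0, p <= 1)
  set.seed(seed)
  pairs <- expand.grid(source = 0:(N - 1), target = 0:(N - 1))
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- stats::runif(nrow(pairs)) < p
  edges <- pairs[keep, ]
  edges$weight <- stats::rnorm(nrow(edges), 0, weight_scale)
  if (kind == "eds") {
    eds_network(N, edges = edges, ...)
  } else {
    dots <- list(...)
    channels <- dots$channels %||% 8
    input_scale <- dots$input_scale %||% 0.5
    n_input <- dots$n_input %||% (N %/% 2)
    W <- matrix(0, N, N)
    if (nrow(edges)) W[cbind(edges$target + 1L, edges$source + 1L)] <- edges$weight
    W_in <- matrix(stats::rnorm(N * channels, 0, input_scale), N, channels)
    erc_network(N, W, W_in,
                bias = dots$bias %||% rep(0, N),
                leak = dots$leak %||% 0.5,
                noise_std = dots$noise_std %||% 1e-3,
                n_input = n_input)
  }
}

#' Derive a component seed from a master seed
#'
#' Deterministic, platform-independent hash of `(master, tag)` into
#' `[1, 2^31 - 2]`, so each named component of an experiment gets its
#' own stable RNG stream.
#'
#' @param master integer master seed.
#' @param tag character component tag.
#' @return Integer child seed.
#' @export
child_seed <- function(master, tag) {
  h <- as.double(master %% 2147483647L)
  for (ch in utf8ToInt(tag)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

#' Run a named experiment from a configuration list
#'
#' Dispatches to the package's experiment drivers and writes every
#' output plus a JSON run record into `out_dir`. The same configuration
#' and seed reproduce identical outputs.
#'
#' Known experiments:
#' \describe{
#'   \item{`kas_build`}{tabulate the inner function; params `gamma`,
#'     `n`, `k`; writes `psi.csv`.}
#'   \item{`kas_reconstruct`}{fit and score the superposition of a
#'     built-in target (`f = "product"` or `"mean"`); writes
#'     `report.json`.}
#'   \item{`landscape_demo`}{attractor-count profile along a coefficient
#'     path; params `start`, `end`, `steps`; writes `profile.csv`.}
#'   \item{`eds_evolve`}{full evolved-network feedback-ablation study
#'     ([heterarchy_experiment()]); writes the evolved network, fitness
#'     history and `report.json`.}
#'   \item{`eds_ablate`}{feedback-ablation experiment on a random or
#'     loaded network; writes per-variant MI series and `report.json`.}
#'   \item{`erc_evolve`}{evolve reservoir wiring; writes fitness history
#'     `history.csv` and the best network.}
#'   \item{`erc_sweep`}{feedback scale-factor sweep of a stored network;
#'     writes `sweep.csv`.}
#' }
#'
#' @param cfg list with at least `experiment`, `seed`, plus
#'   experiment-specific parameters; unknown experiment names are
#'   rejected before any file is written.
#' @param out_dir output directory (created if needed).
#' @return A run-record list (also written as `run_record.json`).
#' @export
run_experiment <- function(cfg, out_dir) {
  known <- c("kas_build", "kas_reconstruct", "landscape_demo",
             "eds_evolve", "eds_ablate", "erc_evolve", "erc_sweep")
  if (is.null(cfg$experiment) || !(cfg$experiment %in% known)) {
    stop("run_experiment: unknown experiment '", cfg$experiment %||% "<missing>",
         "' (known: ", paste(known, collapse = ", "), ")")
  }
  if (is.null(cfg$seed)) stop("run_experiment: seed is mandatory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  files <- switch(cfg$experiment,
    kas_build = {
      tab <- inner_psi(cfg$gamma %||% 10, cfg$n %||% 2, cfg$k %||% 3)
      write_psi_csv(tab, file.path(out_dir, "psi.csv"))
      "psi.csv"
    },
    kas_reconstruct = {
      n <- cfg$n %||% 2
      pars <- kas_constants(n, cfg$m %||% (2 * n), cfg$gamma %||% 10)
      tab <- inner_psi(pars$gamma, n, cfg$k %||% 3)
      f <- switch(cfg$f %||% "product",
                  product = function(X) apply(X, 1, prod),
                  mean = function(X) rowMeans(X),
                  stop("run_experiment: unknown builtin f"))
      rec <- kas_reconstruct(f, pars, tab, test_depth = cfg$test_depth %||% 2)
      jsonlite::write_json(list(sup_error = rec$sup_error, n_test = rec$n_test,
                                gamma = pars$gamma, n = n, k = tab$k),
                           file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA)
      "report.json"
    },
    landscape_demo = {
      prof <- differentiation_path(unlist(cfg$start), unlist(cfg$end),
                                   steps = cfg$steps %||% 50)
      utils::write.csv(prof[, c("step", "count")],
                       file.path(out_dir, "profile.csv"), row.names = FALSE)
      "profile.csv"
    },
    eds_evolve = {
      hx <- heterarchy_experiment(cfg$seed, N = cfg$N %||% 10,
                                  p = cfg$p %||% 0.25)
      write_eds_network(hx$net, file.path(out_dir, "evolved.tsv"))
      jsonlite::write_json(
        list(probe = hx$probe, n_feedback = hx$n_feedback,
             best_fitness = hx$best_fitness,
             decay_all_feedback_removed = hx$decay_all,
             decay_one_feedback_removed = hx$decay_one),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
      c("evolved.tsv", "evolved.tsv.json", "report.json")
    },
    eds_ablate = {
      net <- if (!is.null(cfg$net_tsv)) read_eds_network(cfg$net_tsv)
             else random_network(cfg$N %||% 10, cfg$p %||% 0.25,
                                 seed = child_seed(cfg$seed, "net"),
                                 kind = "eds",
                                 shared_params = do.call(elementary_params,
                                                         cfg$shared_params %||% list(a1 = 1, a2 = 2)))
      pr <- ablation_protocol(seed = child_seed(cfg$seed, "ablate"))
      variants <- cfg$variants %||% list(none = "none", all_feedback = "all_feedback")
      rep <- ablation_experiment(net, cfg$probe %||% 3L, variants, pr)
      outs <- character(0)
      for (nm in names(rep)) {
        f <- paste0("mi_", nm, ".csv")
        write_mi_series(rep[[nm]]$mi, file.path(out_dir, f))
        outs <- c(outs, f)
      }
      jsonlite::write_json(
        lapply(rep, function(r) r[c("variant", "decay_rate", "mean_mi",
                                    "removed", "probe_unreachable")]),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
      c(outs, "report.json")
    },
    erc_evolve = {
      tasks <- make_patterns(seed = child_seed(cfg$seed, "tasks"))
      tmpl <- random_network(cfg$N %||% 60, p = 0,
                             seed = child_seed(cfg$seed, "template"),
                             kind = "erc")
      ga <- ga_config(population = cfg$population %||% 16,
                      generations = cfg$generations %||% 30,
                      seed = child_seed(cfg$seed, "ga"))
      ev <- evolve_erc(tmpl, tasks, ga)
      utils::write.csv(ev$result$history, file.path(out_dir, "history.csv"),
                       row.names = FALSE)
      write_erc_network(ev$final_net, file.path(out_dir, "best.tsv"))
      c("history.csv", "best.tsv", "best.tsv.json")
    },
    erc_sweep = {
      net <- read_erc_network(cfg$net_tsv)
      tasks <- make_patterns(seed = child_seed(cfg$seed, "tasks"))
      sw <- feedback_scale_sweep(net, cfg$s_grid %||% c(0, 0.5, 1, 1.5, 2),
                                 tasks, seed = child_seed(cfg$seed, "noise"))
      utils::write.csv(sw, file.path(out_dir, "sweep.csv"), row.names = FALSE)
      "sweep.csv"
    })
  record <- list(config = cfg,
                 package_version = as.character(utils::packageVersion("csorg")),
                 seed = cfg$seed,
                 started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                 finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 status = "ok",
                 files = as.list(files))
  jsonlite::write_json(record, file.path(out_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(record)
}
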