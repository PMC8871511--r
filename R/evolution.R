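#' Genome for the genetic-algorithm engine
#'
#' A real-valued vector partitioned into named segments (for example the
#' shared map parameters `a1..a6`, the per-unit biases, or the weights of
#' a fixed edge set), each segment with its own box bounds.
#'
#' @param values numeric vector.
#' @param segments named integer vector of segment lengths; must sum to
#'   `length(values)`.
#' @param bounds named list (same names as `segments`) of `c(low, high)`
#'   pairs.
#' @return An object of class `gene`.
#' @export
gene <- function(values, segments = c(all = length(values)),
                 bounds = stats::setNames(rep(list(c(-1, 1)), length(segments)),
                                          names(segments))) {
  stopifnot(sum(segments) == length(values), all(is.finite(values)),
            identical(sort(names(segments)), sort(names(bounds))))
  lo <- rep(vapply(bounds[names(segments)], `[`, numeric(1), 1), segments)
  hi <- rep(vapply(bounds[names(segments)], `[`, numeric(1), 2), segments)
  if (any(values < lo - 1e-12) || any(values > hi + 1e-12)) {
    stop("gene: values outside segment bounds")
  }
  structure(list(values = pmin(pmax(values, lo), hi),
                 segments = segments, bounds = bounds),
            class = "gene")
}

gene_lo <- function(g) rep(vapply(g$bounds[names(g$segments)], `[`, numeric(1), 1),
                           g$segments)
gene_hi <- function(g) rep(vapply(g$bounds[names(g$segments)], `[`, numeric(1), 2),
                           g$segments)

#' Genetic-algorithm configuration
#'
#' @param population population size (>= 2).
#' @param generations number of generations (>= 1).
#' @param mutation_rate per-locus mutation probability.
#' @param mutation_scale mutation standard deviation as a fraction of the
#'   segment's bound range.
#' @param crossover_prob probability that a child is produced by uniform
#'   crossover of two parents (otherwise a copy of one parent).
#' @param elite number of top genes copied unchanged each generation.
#' @param tournament_k tournament size of the selection operator.
#' @param seed RNG seed governing the whole run.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 30, generations = 50, mutation_rate = 0.1,
                      mutation_scale = 0.1, crossover_prob = 0.7, elite = 2,
                      tournament_k = 3, seed = 1L) {
  stopifnot(population >= 2, generations >= 1, elite >= 0,
            elite <= population, mutation_rate >= 0, mutation_rate <= 1,
            mutation_scale > 0, crossover_prob >= 0, crossover_prob <= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 mutation_rate = mutation_rate,
                 mutation_scale = mutation_scale,
                 crossover_prob = crossover_prob,
                 elite = as.integer(elite),
                 tournament_k = as.integer(tournament_k),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Mutation operator
#'
#' Each locus is independently perturbed with probability
#' `cfg$mutation_rate` by a zero-mean normal draw whose standard
#' deviation is `cfg$mutation_scale` times the locus's bound range; the
#' result is clipped to the bounds. Uses the current RNG state.
#'
#' @param g a [gene()].
#' @param cfg a [ga_config()].
#' @return A mutated [gene()].
#' @export
mutate_gene <- function(g, cfg) {
  lo <- gene_lo(g)
  hi <- gene_hi(g)
  n <- length(g$values)
  hit <- stats::runif(n) < cfg$mutation_rate
  v <- g$values
  if (any(hit)) {
    v[hit] <- v[hit] + stats::rnorm(sum(hit), 0,
                                    cfg$mutation_scale * (hi[hit] - lo[hit]))
    v <- pmin(pmax(v, lo), hi)
  }
  g$values <- v
  g
}

#' Uniform crossover operator
#'
#' Each locus of the child is inherited from either parent with equal
#' probability. Parents must share the same layout.
#'
#' @param g1,g2 parent [gene()]s with identical segments and bounds.
#' @return A child [gene()].
#' @export
crossover_genes <- function(g1, g2) {
  if (!identical(g1$segments, g2$segments) || !identical(g1$bounds, g2$bounds)) {
    stop("crossover_genes: gene layouts differ")
  }
  pick <- stats::runif(length(g1$values)) < 0.5
  child <- g1
  child$values <- ifelse(pick, g1$values, g2$values)
  child
}

#' Evolve a population of genes under a fitness function
#'
#' Runs `cfg$generations` rounds of evaluate / elite-copy / tournament
#' select / crossover / mutate. Fitness is maximised; wrap
#' error-minimising objectives with a negation adapter. Non-finite
#' fitness values rank below every finite value (counted in the result's
#' `n_nonfinite`), never crash the run. With `elite >= 1` and a
#' deterministic fitness function the best-fitness history is
#' non-decreasing.
#'
#' @param init list of [gene()]s (any length; resampled with replacement
#'   to `cfg$population` if shorter), or a function `function(i)` that
#'   builds the i-th initial gene.
#' @param fitness function mapping a [gene()] to a numeric scalar.
#' @param cfg a [ga_config()].
#' @return An object of class `evolution_result`: `best_gene`,
#'   `best_fitness`, `history` (data frame `gen`, `best`, `mean`),
#'   `population`, `fitnesses`, `n_nonfinite`.
#' @export
evolve <- function(init, fitness, cfg) {
  set.seed(cfg$seed)
  pop <- if (is.function(init)) {
    lapply(seq_len(cfg$population), init)
  } else {
    if (length(init) >= cfg$population) init[seq_len(cfg$population)]
    else init[sample(seq_along(init), cfg$population, replace = TRUE)]
  }
  history <- data.frame(gen = integer(0), best = numeric(0), mean = numeric(0))
  n_nonfinite <- 0L
  fits <- NULL
  for (gen in seq_len(cfg$generations)) {
    fits <- vapply(pop, function(g) as.numeric(fitness(g)), numeric(1))
    bad <- !is.finite(fits)
    n_nonfinite <- n_nonfinite + sum(bad)
    rank_fit <- fits
    rank_fit[bad] <- -Inf
    history <- rbind(history,
                     data.frame(gen = gen, best = max(rank_fit),
                                mean = mean(fits[!bad])))
    ord <- order(rank_fit, decreasing = TRUE)
    newpop <- pop[ord[seq_len(cfg$elite)]]
    while (length(newpop) < cfg$population) {
      p1 <- tournament_pick(rank_fit, cfg$tournament_k)
      child <- if (stats::runif(1) < cfg$crossover_prob) {
        p2 <- tournament_pick(rank_fit, cfg$tournament_k)
        crossover_genes(pop[[p1]], pop[[p2]])
      } else {
        pop[[p1]]
      }
      newpop <- c(newpop, list(mutate_gene(child, cfg)))
    }
    pop <- newpop
  }
  fits <- vapply(pop, function(g) as.numeric(fitness(g)), numeric(1))
  rank_fit <- ifelse(is.finite(fits), fits, -Inf)
  best <- which.max(rank_fit)
  structure(list(best_gene = pop[[best]],
                 best_fitness = fits[best],
                 history = history,
                 population = pop,
                 fitnesses = fits,
                 n_nonfinite = n_nonfinite),
            class = "evolution_result")
}

tournament_pick <- function(fits, k) {
  cand <- sample.int(length(fits), min(k, length(fits)))
  cand[which.max(fits[cand])]
}

#' @export
print.evolution_result <- function(x, ...) {
  cat("evolution_result:", nrow(x$history), "generations, best fitness",
      signif(x$best_fitness, 5), "\n")
  invisible(x)
}

#' Serialize genes and evolution results to JSON
#'
#' @param x a [gene()] or [evolve()] result.
#' @param path output JSON path.
#' @export
write_gene_json <- function(x, path) {
  jsonlite::write_json(list(values = x$values,
                            segments = as.list(x$segments),
                            bounds = x$bounds),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname write_gene_json
#' @export
read_gene_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- unlist(obj$segments)
  gene(values = obj$values, segments = segs,
       bounds = lapply(obj$bounds, as.numeric))
}
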