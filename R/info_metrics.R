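#' Plug-in histogram mutual information
#'
#' Estimates mutual information (in bits) from the 2-D joint histogram of
#' two equally long samples, using equal-width bins over the observed
#' range of each continuous variable. Integer, factor or character
#' samples are treated as categorical and get one bin per category. A
#' variable with zero range occupies a single bin (contributing zero
#' entropy), so constant inputs give 0 bits rather than an error.
#'
#' @param x,y samples of equal length (numeric, integer, factor or
#'   character).
#' @param bins number of equal-width bins for continuous variables.
#' @param range_x,range_y optional fixed `c(lo, hi)` binning ranges for
#'   continuous variables; by default the observed range is used. A
#'   fixed range measures information at a fixed state resolution, so
#'   trajectories that converge below the bin width genuinely lose
#'   measured information instead of being rescaled.
#' @return Mutual information estimate in bits (always `>= 0`, symmetric
#'   in `x` and `y`).
#' @export
histogram_mi <- function(x, y, bins = 8, range_x = NULL, range_y = NULL) {
  if (length(x) != length(y)) stop("histogram_mi: unequal sample counts")
  if (length(x) < 2) stop("histogram_mi: need at least 2 samples")
  ix <- bin_indices(x, bins, range_x)
  iy <- bin_indices(y, bins, range_y)
  joint <- table(ix, iy) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  prod <- outer(px, py)
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / prod[nz]))
  max(mi, 0)
}

bin_indices <- function(v, bins, rng = NULL) {
  if (is.factor(v) || is.character(v) ||
      (is.null(rng) && is.numeric(v) && all(v == round(v)) &&
       length(unique(v)) <= bins)) {
    return(match(v, sort(unique(v))))
  }
  if (!all(is.finite(v))) stop("histogram_mi: non-finite samples")
  r <- if (is.null(rng)) range(v) else rng
  if (r[1] == r[2]) return(rep(1L, length(v)))
  idx <- floor((v - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin(pmax(idx, 1L), bins)
}

#' Ensemble of trial traces
#'
#' Container for `E` repeated simulations of the same `N`-unit network
#' over `T` steps, optionally labelled by the input pattern identity
#' presented on each trial.
#'
#' @param values numeric array of dimension `E x T x N`.
#' @param labels optional integer vector (length `E`) of pattern
#'   identities.
#' @return An object of class `ensemble_trace`.
#' @export
ensemble_trace <- function(values, labels = NULL) {
  stopifnot(length(dim(values)) == 3, dim(values)[1] >= 2,
            all(is.finite(values)))
  if (!is.null(labels)) stopifnot(length(labels) == dim(values)[1])
  structure(list(values = values, labels = labels,
                 E = dim(values)[1], T = dim(values)[2], N = dim(values)[3]),
            class = "ensemble_trace")
}

#' Time-dependent mutual information
#'
#' For each time step, estimates across trials the mutual information
#' between one unit's state and a reference variable: either the trial's
#' pattern label, or the (possibly delayed) external input value.
#'
#' @param ens an [ensemble_trace()].
#' @param unit 0-based unit index.
#' @param ref `"labels"` to use the per-trial pattern identity, or
#'   `"input"` to use the input value at `t - delay`.
#' @param input `E x T` matrix of per-trial input values (required when
#'   `ref = "input"`).
#' @param bins histogram bins for the unit state.
#' @param delay input delay in steps (only for `ref = "input"`).
#' @param state_range optional fixed binning range for the unit state
#'   (see [histogram_mi()]).
#' @return A data frame of class `mi_series` with columns `t` and `bits`.
#' @export
time_mi <- function(ens, unit, ref = c("labels", "input"), input = NULL,
                    bins = 8, delay = 0, state_range = NULL) {
  stopifnot(inherits(ens, "ensemble_trace"))
  ref <- match.arg(ref)
  if (unit < 0 || unit >= ens$N) stop("time_mi: unit index out of range")
  if (ref == "labels" && is.null(ens$labels)) {
    stop("time_mi: ensemble carries no labels")
  }
  if (ref == "input" && is.null(input)) stop("time_mi: input matrix required")
  bits <- vapply(seq_len(ens$T), function(t) {
    xs <- ens$values[, t, unit + 1L]
    yr <- if (ref == "labels") ens$labels else {
      ti <- t - delay
      if (ti < 1) return(0)
      input[, ti]
    }
    histogram_mi(xs, yr, bins = bins, range_x = state_range)
  }, numeric(1))
  structure(data.frame(t = seq_len(ens$T), bits = bits),
            class = c("mi_series", "data.frame"))
}

#' Vectorised per-timestep mutual-information profile of an ensemble
#'
#' Computes, for every time step and unit at once, the plug-in
#' histogram mutual information (bits) between the unit state across
#' trials and the trial's pattern label — the same estimator as
#' [histogram_mi()], vectorised for use inside fitness evaluations.
#'
#' @param values `E x T x N` numeric array of trial traces.
#' @param labels length-`E` integer label vector.
#' @param bins equal-width state bins.
#' @param state_range optional fixed `c(lo, hi)` binning range shared by
#'   all states (see [histogram_mi()]); default: observed range per
#'   (time, unit) column.
#' @return `T x N` matrix of MI values in bits.
#' @export
ensemble_mi_profile <- function(values, labels, bins = 8,
                                state_range = NULL) {
  d <- dim(values)
  E <- d[1]; M <- d[2] * d[3]
  V <- matrix(values, E, M)
  lab <- match(labels, sort(unique(labels)))
  L <- max(lab)
  if (is.null(state_range)) {
    cmin <- Reduce(pmin, asplit(V, 1))
    cmax <- Reduce(pmax, asplit(V, 1))
  } else {
    cmin <- rep(state_range[1], M)
    cmax <- rep(state_range[2], M)
    V <- pmin(pmax(V, state_range[1]), state_range[2])
  }
  rng <- cmax - cmin
  rng[rng == 0] <- 1  # zero-range column -> single bin, MI 0
  idx <- floor((V - rep(cmin, each = E)) / rep(rng, each = E) * bins) + 1L
  idx <- pmin(idx, bins)
  code <- idx + bins * (lab - 1L) + (bins * L) * rep(seq_len(M) - 1L, each = E)
  C <- array(tabulate(code, nbins = bins * L * M), dim = c(bins, L, M))
  P <- C / E
  px <- apply(P, c(1, 3), sum)                      # bins x M
  py <- apply(P, c(2, 3), sum)                      # L x M
  px3 <- aperm(array(px, c(bins, M, L)), c(1, 3, 2))
  py3 <- aperm(array(py, c(L, M, bins)), c(3, 1, 2))
  term <- array(0, dim(P))
  nz <- P > 0
  term[nz] <- P[nz] * log2(P[nz] / (px3[nz] * py3[nz]))
  bits <- colSums(matrix(term, bins * L, M))
  matrix(pmax(bits, 0), d[2], d[3])
}

#' Modality preference of a unit by shared information
#'
#' Computes the mutual information between a unit's time-averaged state
#' and the class label, separately within the spatial and the temporal
#' trials, and reports which modality shares more information with the
#' unit.
#'
#' @param ens an [ensemble_trace()].
#' @param unit 0-based unit index.
#' @param modality character/factor vector (length `E`) of trial
#'   modalities (`"spatial"` / `"temporal"`).
#' @param class integer vector (length `E`) of class labels.
#' @param bins histogram bins.
#' @return List with `bits_spatial`, `bits_temporal` and `preference`
#'   (`"spatial"`, `"temporal"`, or `"none"` on ties/absence).
#' @export
modality_mi <- function(ens, unit, modality, class, bins = 8) {
  stopifnot(inherits(ens, "ensemble_trace"),
            length(modality) == ens$E, length(class) == ens$E)
  if (unit < 0 || unit >= ens$N) stop("modality_mi: unit index out of range")
  avg <- rowMeans(ens$values[, , unit + 1L, drop = FALSE][, , 1])
  one <- function(mod) {
    sel <- modality == mod
    if (!any(sel)) return(0)
    histogram_mi(avg[sel], class[sel], bins = bins)
  }
  bs <- one("spatial")
  bt <- one("temporal")
  pref <- if (bs > bt) "spatial" else if (bt > bs) "temporal" else "none"
  list(bits_spatial = bs, bits_temporal = bt, preference = pref)
}

#' Log-linear decay rate of a mutual-information series
#'
#' Fits a least-squares line to `log(bits + eps_floor)` over a time
#' window and returns the negated slope, so a larger rate means faster
#' decay (natural-log units per step).
#'
#' @param series an [time_mi()] result (`mi_series`), or any data frame
#'   with columns `t` and `bits`.
#' @param window length-2 integer time window `c(t_from, t_to)`.
#' @param eps_floor additive floor inside the logarithm.
#' @return Numeric decay rate; attribute `degenerate` is `TRUE` when the
#'   window contains no positive MI values (rate reported as 0).
#' @export
decay_rate <- function(series, window = range(series$t), eps_floor = 1e-6) {
  sel <- series$t >= window[1] & series$t <= window[2]
  if (sum(sel) < 3) stop("decay_rate: window must contain at least 3 points")
  tt <- series$t[sel]
  bb <- series$bits[sel]
  if (all(bb <= 0)) {
    return(structure(0, degenerate = TRUE))
  }
  fit <- stats::lm.fit(cbind(1, tt), log(bb + eps_floor))
  structure(-unname(fit$coefficients[2]), degenerate = FALSE)
}

#' Save / load a mutual-information series as CSV
#'
#' @param series an `mi_series` data frame.
#' @param path CSV path (columns `t,bits`).
#' @export
write_mi_series <- function(series, path) {
  utils::write.csv(series[, c("t", "bits")], path, row.names = FALSE)
  invisible(series)
}

#' @rdname write_mi_series
#' @export
read_mi_series <- function(path) {
  structure(utils::read.csv(path), class = c("mi_series", "data.frame"))
}
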