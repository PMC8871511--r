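test_that("histogram MI handles dependence, independence and degeneracy", {
  set.seed(1)
  x <- sample(0:1, 10000, replace = TRUE)
  expect_equal(histogram_mi(x, x), 1, tolerance = 0.02)
  expect_equal(histogram_mi(rep(2.5, 100), runif(100)), 0)

  # independent streams: the Miller-Madow bias bound is the expectation
  # of the plug-in estimate; allow its 3-sigma chi-square sampling envelope
  mm <- (8 - 1)^2 / (2 * log(2) * 10000)
  se <- sqrt(2 * (8 - 1)^2) / (2 * log(2) * 10000)
  expect_lte(mean(replicate(5, histogram_mi(runif(10000), runif(10000)))),
             mm + 3 * se / sqrt(5))

  expect_error(histogram_mi(1:5, 1:4), "unequal")
  expect_error(histogram_mi(1, 1), "at least 2")
})

test_that("histogram MI is symmetric and bounded by the marginal entropies", {
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(300)
    y <- 0.5 * x + rnorm(300)
    expect_identical(histogram_mi(x, y), histogram_mi(y, x))
    hx <- histogram_mi(x, x)
    hy <- histogram_mi(y, y)
    expect_lte(histogram_mi(x, y), min(hx, hy) + 1e-12)
  }
})

test_that("MI of independent streams shrinks with sample size", {
  set.seed(3)
  mi_at <- function(n) {
    mean(replicate(5, histogram_mi(runif(n), runif(n))))
  }
  expect_lt(mi_at(8000), mi_at(200))
})

test_that("time-dependent MI tracks the per-step estimator and its bounds", {
  set.seed(4)
  E <- 60; T <- 15; N <- 2
  vals <- array(rnorm(E * T * N), c(E, T, N))
  labels <- sample(0:2, E, replace = TRUE)
  # plant label-determined states at one unit from t = 6 on
  vals[, 6:T, 2] <- matrix(labels, E, T - 5) + 1e-9 * vals[, 6:T, 2]
  ens <- ensemble_trace(vals, labels)
  s <- time_mi(ens, 1, ref = "labels")
  expect_true(all(s$bits >= 0))
  expect_true(all(s$bits <= log2(3) + 1e-12))
  # per-step oracle
  for (t in c(3, 10)) {
    expect_equal(s$bits[t], histogram_mi(vals[, t, 2], labels))
  }
  ent <- histogram_mi(labels, labels)
  expect_equal(s$bits[6:T], rep(ent, T - 5), tolerance = 1e-6)

  # identical labels carry no information
  same <- ensemble_trace(vals, rep(1L, E))
  expect_true(all(time_mi(same, 0, ref = "labels")$bits == 0))

  expect_error(time_mi(ens, 5, ref = "labels"), "out of range")
})

test_that("vectorised MI profile equals the per-step estimator exactly", {
  set.seed(5)
  vals <- array(rnorm(40 * 12 * 3), c(40, 12, 3))
  labels <- sample(0:3, 40, replace = TRUE)
  prof <- ensemble_mi_profile(vals, labels)
  ens <- ensemble_trace(vals, labels)
  for (u in 0:2) {
    expect_equal(prof[, u + 1], time_mi(ens, u, ref = "labels")$bits)
  }
  # fixed-range variant agrees with the range-passing estimator
  prof_f <- ensemble_mi_profile(vals, labels, state_range = c(-4, 4))
  expect_equal(prof_f[, 2],
               time_mi(ens, 1, ref = "labels", state_range = c(-4, 4))$bits)
})

test_that("modality preference follows the planted dependence", {
  set.seed(6)
  E <- 120
  modality <- rep(c("spatial", "temporal"), each = E / 2)
  class <- rep(rep(0:3, each = E / 8), 2)
  vals <- array(rnorm(E * 10 * 1, sd = 0.01), c(E, 10, 1))
  sel <- modality == "spatial"
  vals[sel, , 1] <- vals[sel, , 1] + class[sel]
  ens <- ensemble_trace(vals, class)
  r <- modality_mi(ens, 0, modality, class)
  expect_equal(r$preference, "spatial")
  expect_gt(r$bits_spatial, r$bits_temporal)
  # swapping the modality labels swaps the pair
  swapped <- ifelse(modality == "spatial", "temporal", "spatial")
  r2 <- modality_mi(ens, 0, swapped, class)
  expect_equal(r2$bits_temporal, r$bits_spatial)
  expect_equal(r2$bits_spatial, r$bits_temporal)
  # constant unit shares nothing
  cens <- ensemble_trace(array(1, c(E, 10, 1)), class)
  rc <- modality_mi(cens, 0, modality, class)
  expect_equal(c(rc$bits_spatial, rc$bits_temporal), c(0, 0))
  expect_equal(rc$preference, "none")
})

test_that("decay rate recovers planted exponential slopes", {
  s <- structure(data.frame(t = 1:50, bits = 2^-(1:50)),
                 class = c("mi_series", "data.frame"))
  # closed-form slope, up to the documented additive log floor (1e-6)
  expect_equal(as.numeric(decay_rate(s, c(1, 10))), log(2), tolerance = 1e-3)
  # halving the decay time doubles the rate (floor-limited precision)
  s2 <- transform(s, bits = 4^-(1:50))
  expect_equal(as.numeric(decay_rate(s2, c(1, 8))) /
                 as.numeric(decay_rate(s, c(1, 8))), 2, tolerance = 0.01)
  # constant series has zero rate; all-zero series is flagged
  sc <- transform(s, bits = 0.7)
  expect_equal(as.numeric(decay_rate(sc, c(1, 50))), 0)
  sz <- transform(s, bits = 0)
  r <- decay_rate(sz, c(1, 50))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  expect_error(decay_rate(s, c(1, 2)), "at least 3")
})

test_that("MI series round-trip through CSV", {
  dir <- withr::local_tempdir()
  s <- structure(data.frame(t = 1:5, bits = c(1, 0.5, 0.25, 0.2, 0)),
                 class = c("mi_series", "data.frame"))
  f <- file.path(dir, "mi.csv")
  write_mi_series(s, f)
  expect_equal(read_mi_series(f)$bits, s$bits)
})
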