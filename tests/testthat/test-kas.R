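test_that("digit-weight exponent matches its geometric-series closed form", {
  expect_equal(beta_n(2, 1), 1)
  expect_equal(beta_n(2, 2), 3)
  expect_equal(beta_n(3, 2), 4)
  expect_equal(beta_n(2, 1:5), c(1, 3, 7, 15, 31))
  # closed form vs direct geometric sum
  for (n in 2:4) for (l in 1:6) {
    expect_equal(beta_n(n, l), sum(n^(0:(l - 1))))
  }
  expect_error(beta_n(2, 0), "l must be")
})

test_that("constants obey the admissibility inequalities and printed formulas", {
  expect_error(kas_constants(2, 3, 10), "m >= 2n")
  expect_error(kas_constants(2, 4, 5), "gamma >= m \\+ 2")
  kp <- kas_constants(2, 4, 6)
  expect_s3_class(kp, "kas_params")

  kp10 <- kas_constants(2, 4, 10)
  expect_equal(kp10$c, 1 / 90)
  expect_equal(kp10$lambda[1], 1)
  # truncated series oracle: lambda_2 = 10^-1 + 10^-3 + 10^-7 + 10^-15
  expect_equal(kp10$lambda[2], 1e-1 + 1e-3 + 1e-7 + 1e-15, tolerance = 1e-15)
  expect_equal(kp10$alpha, log10(2))
  expect_equal(kp10$nu, 2^(-log10(2)) * 13)

  # lambda sequence: lambda_1 = 1, in (0, 1], strictly decreasing
  for (n in 2:4) {
    kp <- kas_constants(n, 2 * n, 2 * n + 2)
    expect_equal(kp$lambda[1], 1)
    expect_true(all(kp$lambda > 0 & kp$lambda <= 1))
    expect_true(all(diff(kp$lambda) < 0))
  }
})

test_that("inner function table is monotone, in range and refinement-consistent", {
  for (gam in c(6, 10)) {
    tab <- inner_psi(gam, 2, 2)
    expect_true(all(diff(tab$psi) > 0))
    expect_true(all(tab$psi >= 0 & tab$psi <= 2))
    expect_equal(tab$psi[1], 0)
    expect_equal(tab$psi[length(tab$psi)], 2)
    # depth-k values reappear unchanged at depth k+1
    finer <- inner_psi(gam, 2, 3)
    idx <- match(round(tab$x, 12), round(finer$x, 12))
    expect_false(anyNA(idx))
    expect_equal(finer$psi[idx], tab$psi)
  }
  # unit translation on [1, 2]
  tab <- inner_psi(10, 2, 2)
  lower <- tab$x < 1 - 1e-12
  expect_equal(psi_eval(tab, tab$x[lower] + 1), tab$psi[lower] + 1)
})

test_that("Hoelder check passes for the constructed table and rejects violations", {
  # constant table passes for any nu > 0
  const <- structure(list(x = seq(0, 2, 0.1), psi = rep(1, 21),
                          gamma = 10L, n = 2L, k = 1L),
                     class = "inner_function_table")
  expect_true(check_holder(const, 0.01, 0.5)$pass)

  # identity on [0, 1] with alpha = 0.5, nu = 1: max ratio = max dx^(1-a) = 1
  ident <- structure(list(x = seq(0, 1, 0.01), psi = seq(0, 1, 0.01),
                          gamma = 10L, n = 2L, k = 2L),
                     class = "inner_function_table")
  ch <- check_holder(ident, 1, 0.5)
  expect_true(ch$pass)
  expect_equal(ch$max_ratio, 1, tolerance = 1e-12)
  # ... and fails when nu is below the achieved ratio
  expect_false(check_holder(ident, 0.5, 0.5)$pass)

  kp <- kas_constants(2, 4, 10)
  expect_true(check_holder(inner_psi(10, 2, 2), kp$nu, kp$alpha)$pass)
})

test_that("inner map is injective on the grid and linear in the table", {
  kp <- kas_constants(2, 4, 6)
  tab <- inner_psi(6, 2, 2)
  expect_equal(inner_map(c(0, 0), kp, tab)[1], 0)
  expect_length(inner_map(c(0.5, 0.5), kp, tab), kp$m + 1)
  expect_error(inner_map(c(1.5, 0), kp, tab), "outside")

  # exhaustive injectivity on the depth-2 grid (36^2 points, gamma = 6)
  X <- as.matrix(expand.grid(x1 = (0:35) / 36, x2 = (0:35) / 36))
  Z <- inner_map(X, kp, tab)
  expect_equal(nrow(unique(round(Z, 12))), nrow(X))
})

test_that("outer fitting is exact on the training grid", {
  kp <- kas_constants(2, 4, 6)
  tab <- inner_psi(6, 2, 2)

  f0 <- function(X) rep(0, nrow(X))
  out0 <- fit_outer(f0, kp, tab)
  expect_equal(kas_eval(out0, c(0.3, 0.7), tab), 0)

  fK <- function(X) rep(2.5, nrow(X))
  outK <- fit_outer(fK, kp, tab)
  Xg <- kas_grid(2, 6, 2)
  expect_equal(kas_eval(outK, Xg, tab), rep(2.5, nrow(Xg)), tolerance = 1e-9)

  fmean <- function(X) rowMeans(X)
  outm <- fit_outer(fmean, kp, tab)
  expect_lt(max(abs(kas_eval(outm, Xg, tab) - rowMeans(Xg))), 1e-9)

  expect_error(fit_outer(function(X) rep(NaN, nrow(X)), kp, tab),
               "non-finite")
})

test_that("reconstruction error is nonnegative and improves with depth", {
  kp <- kas_constants(2, 4, 6)
  fprod <- function(X) X[, 1] * X[, 2]
  errs <- vapply(1:3, function(k) {
    kas_reconstruct(fprod, kp, inner_psi(6, 2, k), test_depth = 2)$sup_error
  }, numeric(1))
  expect_true(all(errs >= 0))
  expect_lt(errs[3], errs[1])
})

test_that("relu clamps at zero", {
  expect_equal(relu(c(-1, 0, 2)), c(0, 0, 2))
  expect_error(relu(NA_real_), "finite")
})

test_that("inner-function tables export as x,psi CSV", {
  dir <- withr::local_tempdir()
  tab <- inner_psi(6, 2, 1)
  f <- file.path(dir, "psi.csv")
  write_psi_csv(tab, f)
  d <- read.csv(f)
  expect_equal(d$psi, tab$psi)
})
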