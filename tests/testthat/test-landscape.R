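test_that("landscape evaluation agrees between forms", {
  expect_equal(landscape_S(0, b = 3, n = 4), 1)
  expect_equal(landscape_S(1, b = 0, n = 4), 2)
  y <- seq(-2, 2, 0.25)
  expect_equal(landscape_S(y, b = -1.5, n = 4),
               eval_landscape(landscape_S_coeffs(-1.5, 4), y))
  expect_equal(landscape_D(y, c(0.5, -2), confine = 4),
               eval_landscape(landscape_D_coeffs(c(0.5, -2), 4), y))
  expect_error(landscape_D(y, c(1, 1), confine = 5), "even")
  expect_error(landscape_D(y, c(1, 1, 1, 1), confine = 4), "exceed")
})

test_that("stem-index table is reproducible and Lipschitz in its parameter", {
  t1 <- stem_index(0.3)
  t2 <- stem_index(0.3)
  expect_identical(t1, t2)
  expect_equal(attr(t1, "b"), 0.3)
  expect_equal(t1$S, landscape_S(t1$y, 0.3, 4))
  # |S(y; b) - S(y; b + db)| = |db||y| <= db * max|y|
  db <- 1e-3
  t3 <- stem_index(0.3 + db)
  expect_lte(max(abs(t3$S - t1$S)), db * max(abs(t1$y)) + 1e-12)
})

test_that("attractor counting matches calculus on canonical wells", {
  one <- count_attractors(poly_landscape(c(0, 0, 1), c(-1, 1)))
  expect_equal(one$count, 1)
  expect_equal(one$minima$location, 0, tolerance = 1e-8)

  two <- count_attractors(poly_landscape(c(0, 0, -2, 0, 1), c(-2, 2)))
  expect_equal(two$count, 2)
  expect_equal(sort(two$minima$location), c(-1, 1), tolerance = 1e-8)

  mono <- count_attractors(poly_landscape(c(0, 1), c(0, 1)))
  expect_equal(mono$count, 0)
  expect_equal(mono$boundary, "left")

  # pure even confining power has a single minimum at 0
  d0 <- count_attractors(poly_landscape(landscape_D_coeffs(c(0, 0), 4),
                                        c(-2, 2)))
  expect_equal(d0$count, 1)
  expect_equal(d0$minima$location, 0, tolerance = 1e-8)
})

test_that("attractor counting agrees with the polynomial-root oracle", {
  set.seed(21)
  for (i in 1:100) {
    deg <- sample(2:6, 1)
    cf <- c(rnorm(deg, sd = 1.5), runif(1, 0.2, 1.5) * (-1)^rbinom(1, 1, 0.3))
    # keep the landscape confined so minima are interior and well-separated
    if (deg %% 2 == 1 || cf[deg + 1] < 0) cf <- c(cf, 0.5)
    L <- poly_landscape(cf, c(-3, 3), grid = 2048)
    att <- count_attractors(L)
    orc <- poly_minima_oracle(cf, c(-3, 3))
    expect_equal(att$count, length(orc), info = paste("instance", i))
    if (length(orc)) {
      expect_equal(sort(att$minima$location), sort(orc), tolerance = 1e-4)
    }
  }
})

test_that("gradient descent is Lyapunov-descending and finds the right basin", {
  L <- poly_landscape(c(0, 0, -2, 0, 1), c(-2, 2))
  # start at a minimum: stays there
  g0 <- gradient_flow(L, 1)
  expect_lt(abs(g0$y_final - 1), 1e-12)
  # from y0 = 0.1 the initial gradient points to the +1 well
  g1 <- gradient_flow(L, 0.1)
  expect_equal(g1$y_final, 1, tolerance = 1e-4)
  expect_equal(g1$basin, which.min(abs(count_attractors(L)$minima$location - 1)))
  vals <- eval_landscape(L, g1$trajectory)
  expect_true(all(diff(vals) <= 1e-12))
  # divergence outside the interval is labelled escaped
  Lb <- poly_landscape(c(0, -1), c(-1, 1))  # constant negative slope
  ge <- gradient_flow(Lb, 0.9, step = 0.5)
  expect_equal(ge$basin, "escaped")
})

test_that("coefficient-path morphs report their bifurcations", {
  # constant path: constant count
  cf <- c(0, 0, 1)
  pc <- differentiation_path(cf, cf, steps = 5)
  expect_true(all(pc$count == 1))
  expect_length(attr(pc, "transitions"), 0)

  # pitchfork: single well to symmetric double well on the quartic family
  pq <- differentiation_path(c(0, 0, 2, 0, 1), c(0, 0, -2, 0, 1),
                             steps = 41, interval = c(-2, 2))
  expect_equal(pq$count[1], 1)
  expect_equal(pq$count[41], 2)
  expect_true(any(diff(pq$count) == 1))

  # sextic with derivative roots at 0, +-1, +-2: three wells
  # D'(y) = 6 y (y^2 - 1)(y^2 - 4) -> integrate for coefficients
  sext <- c(0, 0, 6, 0, -7.5 / 2 * 2, 0, 1)  # 1 y^6 - 7.5 y^4 + 12 y^2... build below
  dcf <- c(0, 24, 0, -30, 0, 6)                 # derivative coefficients
  cf6 <- c(0, dcf / seq_along(dcf))             # antiderivative, constant 0
  expect_equal(length(cf6), 7)
  oracle <- poly_minima_oracle(cf6, c(-3, 3))
  expect_equal(sort(oracle), c(-2, 0, 2), tolerance = 1e-6)
  p3 <- differentiation_path(c(0, 0, 1, 0, 0, 0, 0.01), cf6, steps = 30)
  expect_equal(p3$count[1], 1)
  expect_equal(p3$count[30], 3)
  # the profile only changes at reported transition indices
  tr <- attr(p3, "transitions")
  expect_equal(which(diff(p3$count) != 0) + 1L, tr)
})

test_that("index transform applies the inner function coordinate-wise", {
  kp <- kas_constants(2, 4, 6)
  tab <- inner_psi(6, 2, 2)
  r0 <- index_transform(c(0, 0), kp, tab)
  expect_equal(r0$psi, c(0, 0))
  expect_equal(r0$z[1], 0)
  r <- index_transform(c(0.25, 0.75), kp, tab)
  expect_equal(r$psi, psi_eval(tab, c(0.25, 0.75)))
  expect_equal(r$z, inner_map(c(0.25, 0.75), kp, tab))
  # monotone in each index
  r2 <- index_transform(c(0.30, 0.75), kp, tab)
  expect_gte(r2$psi[1], r$psi[1])
  expect_error(index_transform(c(-0.1, 0.5), kp, tab), "\\[0, 1\\]")
  expect_error(index_transform(c(0.5, 0.5, 0.5), kp, tab), "n = 2")
})
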