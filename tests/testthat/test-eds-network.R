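test_that("degenerate networks simulate to the expected traces", {
  z <- eds_network(3)
  tr <- simulate_network(z, T_steps = 10, x0 = c(0.1, -0.1, 0))
  expect_true(all(tr == 0))

  # N = 1, no edges: equals scalar iteration of the map
  p <- elementary_params(a1 = 0.8, a2 = 2, a3 = 0.1, b = 0.05)
  n1 <- eds_network(1, shared_params = p, biases = 0.05)
  tr1 <- simulate_network(n1, T_steps = 50, x0 = 0.3)
  expect_equal(as.numeric(tr1),
               scalar_iterate_oracle(0.3, unlist(p[1:6]), 0.05, 50))
})

test_that("simulated states respect the tanh amplitude bound", {
  set.seed(7)
  for (i in 1:10) {
    net <- random_network(6, 0.4, seed = i, kind = "eds",
                          shared_params = elementary_params(
                            a1 = runif(1, -2, 2), a2 = runif(1, 0, 4),
                            a3 = runif(1, -1, 1), a4 = runif(1, -2, 2),
                            a5 = runif(1, 0, 4), a6 = runif(1, -1, 1)),
                          biases = runif(6, -1, 1))
    inp <- make_input_signal("binary", 40, seed = i)
    tr <- simulate_network(net, inp, T_steps = 40, seed = i)
    bound <- abs(net$shared_params$a1) + abs(net$shared_params$a4) +
      matrix(abs(net$biases), 40, 6, byrow = TRUE)
    expect_true(all(abs(tr) <= bound + 1e-12))
  }
})

test_that("simulation is deterministic and permutation-equivariant", {
  net <- random_network(5, 0.5, seed = 3, kind = "eds",
                        shared_params = elementary_params(a1 = 0.9, a2 = 1),
                        biases = seq(-0.2, 0.2, length.out = 5))
  inp <- make_input_signal("sine", 30, list(period = 8), seed = 1)
  a <- simulate_network(net, inp, 30, seed = 42)
  b <- simulate_network(net, inp, 30, seed = 42)
  expect_identical(a, b)

  # relabel units by a permutation; trace columns must permute with them
  perm <- c(2L, 0L, 4L, 1L, 3L)  # perm[k+1] = new index of old unit k
  pe <- net$edges
  pe$source <- perm[pe$source + 1L]
  pe$target <- perm[pe$target + 1L]
  pnet <- eds_network(5, pe, net$shared_params,
                      biases = net$biases[order(perm)],
                      receiver = perm[net$receiver + 1L],
                      input_gain = net$input_gain)
  x0 <- c(0.05, -0.02, 0.08, 0, -0.06)
  t1 <- simulate_network(net, inp, 20, x0 = x0)
  t2 <- simulate_network(pnet, inp, 20, x0 = x0[order(perm)])
  expect_equal(unclass(t2)[, perm + 1L], unclass(t1), ignore_attr = TRUE)
})

test_that("input shorter than the simulation is rejected", {
  net <- eds_network(2)
  expect_error(simulate_network(net, input = rep(1, 5), T_steps = 10),
               "shorter")
})

test_that("self-edges, bad indices and duplicates are rejected", {
  expect_error(eds_network(3, data.frame(source = 1, target = 1, weight = 1)),
               "self-edges")
  expect_error(eds_network(3, data.frame(source = 0, target = 3, weight = 1)),
               "out of range")
  expect_error(eds_network(3, data.frame(source = c(0, 0), target = c(1, 1),
                                         weight = c(1, 2))),
               "duplicate")
})

test_that("network and trace files round-trip", {
  dir <- withr::local_tempdir()
  net <- random_network(6, 0.4, seed = 11, kind = "eds",
                        shared_params = elementary_params(a1 = 1.1, a2 = 2.5,
                                                          a4 = 0.3, a5 = 1),
                        biases = runif(6, -1, 1), input_gain = 1.5)
  tsv <- file.path(dir, "net.tsv")
  write_eds_network(net, tsv)
  back <- read_eds_network(tsv)
  expect_equal(back$N, net$N)
  expect_equal(back$edges[order(back$edges$source, back$edges$target), ],
               net$edges[order(net$edges$source, net$edges$target), ],
               ignore_attr = TRUE)
  expect_equal(back$biases, net$biases)
  expect_equal(unclass(back$shared_params), unclass(net$shared_params))

  tr <- simulate_network(net, T_steps = 15, seed = 2)
  csv <- file.path(dir, "trace.csv")
  write_trace_csv(tr, csv)
  tr2 <- read_trace_csv(csv)
  expect_equal(unclass(tr2), unclass(tr), ignore_attr = TRUE)
})

test_that("ensemble simulation matches single-trial simulation", {
  net <- random_network(4, 0.5, seed = 5, kind = "eds",
                        shared_params = elementary_params(a1 = 0.9, a2 = 1),
                        biases = c(0.1, -0.1, 0.2, 0))
  labels <- c(0L, 3L)
  tr <- simulate_eds_ensemble(net, labels, P = 4, T_in = 10, T_steps = 25,
                              seed = 8)
  expect_equal(dim(tr), c(2, 25, 4))
  # trial 1 re-simulated with the constant-level input it received
  set.seed(8)
  X0 <- matrix(runif(2 * 4, -0.1, 0.1), 2, 4)
  lvl <- -1 + 2 * labels / 3
  inp <- c(rep(lvl[1], 10), rep(0, 15))
  t1 <- simulate_network(net, inp, 25, x0 = X0[1, ])
  expect_equal(tr[1, , ], unclass(t1), ignore_attr = TRUE)
})
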