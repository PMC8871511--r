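tiny_erc <- function(N = 6, seed = 1, noise = 0) {
  random_network(N, 0.5, seed = seed, kind = "erc", noise_std = noise,
                 channels = 3)
}

test_that("reservoir step reduces correctly in the leak limits", {
  net <- tiny_erc()
  x <- runif(net$N, -1, 1)

  net0 <- net; net0$leak <- rep(1e-9, net$N)  # alpha -> 0: near identity
  expect_equal(reservoir_step(x, net0), x, tolerance = 1e-6)

  net1 <- net; net1$W[] <- 0; net1$bias[] <- 0; net1$leak <- rep(1, net$N)
  expect_equal(reservoir_step(x, net1), tanh(0 * x), ignore_attr = TRUE)

  expect_error(reservoir_step(x, net, input_row = 1:5), "dimension")
})

test_that("noise-free states are eventually bounded by one", {
  net <- tiny_erc(seed = 2)
  inp <- matrix(rnorm(40 * 3), 40, 3)
  st <- run_trial(net, inp, washout = 5)
  expect_equal(dim(st), c(35, net$N))
  expect_true(all(abs(st) <= 1 + 1e-12))
})

test_that("echo-state contraction: trajectories under shared input converge", {
  set.seed(3)
  N <- 8
  W <- matrix(rnorm(N * N, 0, 0.2), N, N)
  W <- W / (1.2 * max(rowSums(abs(W))))  # row sums < 1
  net <- erc_network(N, W, matrix(0.5, N, 2), leak = 1, noise_std = 0)
  inp <- matrix(rnorm(60 * 2), 60, 2)
  x1 <- runif(N, -1, 1); x2 <- runif(N, -1, 1)
  for (t in 1:60) {
    x1 <- reservoir_step(x1, net, inp[t, ])
    x2 <- reservoir_step(x2, net, inp[t, ])
  }
  expect_lt(max(abs(x1 - x2)), 1e-6)
})

test_that("ridge readout solves its normal equations and shrinks with lambda", {
  set.seed(4)
  S <- matrix(rnorm(60 * 5), 60, 5)
  W0 <- matrix(rnorm(5 * 3), 5, 3)
  expect_equal(train_readout(S, matrix(0, 60, 3), ridge = 0.1),
               matrix(0, 5, 3), ignore_attr = TRUE)
  # planted solution recovered at tiny ridge
  W <- train_readout(S, S %*% W0, ridge = 1e-10)
  expect_equal(W, W0, tolerance = 1e-6, ignore_attr = TRUE)
  # stationarity of the normal equations on random instances
  Y <- matrix(rnorm(60 * 3), 60, 3)
  for (lam in c(1e-4, 0.1, 10)) {
    Wl <- train_readout(S, Y, ridge = lam)
    resid <- crossprod(S, S %*% Wl - Y) + lam * Wl
    expect_lt(max(abs(resid)), 1e-6)
  }
  # Frobenius norm shrinks monotonically in lambda
  norms <- vapply(c(0.01, 1, 100),
                  function(l) sqrt(sum(train_readout(S, Y, l)^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
  # rank-deficient, lambda = 0: minimum-norm least-squares solution
  Sr <- cbind(S[, 1:2], S[, 1] + S[, 2])
  Wm <- train_readout(Sr, Y, ridge = 0)
  expect_lt(max(abs(crossprod(Sr, Sr %*% Wm - Y))), 1e-6)
})

test_that("evaluation is at chance for untrained random readouts", {
  set.seed(5)
  tasks <- make_patterns(n_spatial = 4, n_temporal = 0, trials_per_class = 30,
                         T_steps = 30, seed = 6)
  net <- random_network(20, 0.2, kind = "erc", seed = 7, noise_std = 0.3)
  rec <- csorg:::run_erc_trials(net, tasks$inputs, washout = 5, window = 10,
                                seed = 8)
  # a fixed random readout maps each class prototype deterministically,
  # so chance level emerges over many independent readouts, not trials
  accs <- replicate(60, {
    Wr <- matrix(rnorm(length(net$output_units) * 4), ncol = 4)
    pred <- vapply(seq_len(dim(rec)[1]), function(e) {
      which.max(colMeans(t(rec[e, net$output_units + 1L, ]) %*% Wr))
    }, integer(1))
    mean(pred == tasks$info$class)
  })
  expect_lt(abs(mean(accs) - 0.25), 0.12)
})

test_that("trained readouts separate the task set far above chance", {
  tasks <- make_patterns(trials_per_class = 8, seed = 9)
  net <- random_network(40, 0.1, kind = "erc", seed = 10)
  r <- erc_fit_eval(net, tasks, seed = 11)
  expect_true(all(r$accuracy >= 0 & r$accuracy <= 100))
  expect_gt(r$accuracy[["spatial"]], 50)  # constant patterns are easy
})

test_that("structure statistics count a hand-built toy exactly", {
  N <- 4
  W <- matrix(0, N, N)
  # partition: units 1:2 input layer, 3:4 output layer
  W[3, 1] <- 0.5              # input -> output: feedforward
  W[1, 3] <- -0.2; W[2, 4] <- 0.1  # output -> input: feedback x2
  W[2, 1] <- 0.3              # within input
  net <- erc_network(N, W, matrix(0, N, 1), n_input = 2)
  st <- structure_stats(net)
  expect_equal(st$count[st$class == "feedforward"], 1)
  expect_equal(st$count[st$class == "feedback"], 2)
  expect_equal(st$count[st$class == "within_input"], 1)
  expect_equal(st$count[st$class == "within_output"], 0)
  expect_equal(st$count[st$class == "total"], 4)
  expect_equal(st$weight_sum[st$class == "feedback"], 0.3)
  # below-threshold weights count as absent
  W[4, 2] <- 1e-5
  st2 <- structure_stats(erc_network(N, W, matrix(0, N, 1), n_input = 2))
  expect_equal(st2$count[st2$class == "total"], 4)
  # empty network: all zeros
  st0 <- structure_stats(erc_network(N, matrix(0, N, N), matrix(0, N, 1),
                                     n_input = 2))
  expect_true(all(st0$count == 0))
})

test_that("feedback scaling at s = 1 reproduces the reference exactly", {
  tasks <- make_patterns(trials_per_class = 6, seed = 12)
  net <- random_network(30, 0.15, kind = "erc", seed = 13)
  sw <- feedback_scale_sweep(net, c(0, 1), tasks, seed = 14)
  expect_equal(sw$rel_spatial[sw$s == 1], 100)
  expect_equal(sw$rel_temporal[sw$s == 1], 100)
  # s = 0 equals evaluating the feedback-ablated network
  W0 <- net$W
  W0[net$input_units + 1L, net$output_units + 1L] <- 0
  net0 <- erc_network(net$N, W0, net$W_in, net$bias, net$leak,
                      net$noise_std, net$n_input)
  r0 <- erc_fit_eval(net0, tasks, seed = 14)
  expect_equal(unname(sw$acc_spatial[sw$s == 0]),
               unname(r0$accuracy[["spatial"]]))
})

test_that("reservoir networks round-trip through TSV + JSON", {
  dir <- withr::local_tempdir()
  net <- tiny_erc(seed = 15, noise = 0.01)
  f <- file.path(dir, "erc.tsv")
  write_erc_network(net, f)
  b <- read_erc_network(f)
  expect_equal(b$W, net$W)
  expect_equal(b$W_in, net$W_in)
  expect_equal(b$leak, net$leak)
  expect_equal(b$n_input, net$n_input)
  expect_equal(b$noise_std, net$noise_std)
})
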