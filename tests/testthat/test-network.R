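test_that("feedforward pass reproduces simple closed forms", {
  net <- layered_network(c(3, 4, 2), seed = 1)
  for (l in 1:2) net$W[[l]][] <- 0
  ff <- feedforward_pass(net, c(0.3, 0.9, 0.1))
  expect_equal(ff$rates[[2]], rep(0.5, 4))   # sigmoid(0)
  expect_equal(ff$rates[[3]], rep(0.5, 2))

  net1 <- layered_network(c(1, 1), activation = "linear", seed = 1)
  net1$W[[1]][] <- 0.5
  expect_equal(feedforward_pass(net1, 1.0)$rates[[2]], 0.5)
})

test_that("feedforward pass equals the open-loop fixed point of the dynamics", {
  net <- make_net(c(2, 5, 3), seed = 7)
  x <- c(0.8, 0.2)
  ff <- feedforward_pass(net, x)
  traj <- integrate_dynamics(net, x, duration = 40, dt = 0.01)
  Tn <- n_steps(traj)
  for (l in 2:3) {
    expect_equal(traj$r[[l]][Tn, ], ff$rates[[l]], tolerance = 1e-6)
  }
})

test_that("single-neuron dynamics converge to the closed-form fixed point", {
  # v* = w_A r_A + w_B r_B + c with unit time constant
  net <- layered_network(c(2, 1), seed = 1)
  net$W[[1]][] <- c(0.5, 0)
  traj <- integrate_dynamics(net, c(1, 0), duration = 10, dt = 0.01)
  Tn <- n_steps(traj)
  expect_equal(traj$v[[2]][Tn, ], 0.5, tolerance = 1e-4)
  expect_equal(traj$r[[2]][Tn, ], 1 / (1 + exp(-0.5)), tolerance = 1e-4)
})

test_that("constant feedback shifts the fixed point to drive + Qc", {
  net <- make_net(c(2, 4, 2), seed = 3)
  c0 <- c(0.4, -0.2)
  traj <- integrate_dynamics(net, c(0.5, 0.5),
                             feedback = function(step, rates) c0,
                             duration = 40, dt = 0.01)
  # oracle: damped fixed-point iteration of v = W r_pre + Q c0
  blocks <- dhdfc:::q_row_blocks(net)
  qc <- drop(net$Q %*% c0)
  v2 <- rep(0, 4); v3 <- rep(0, 2)
  for (i in 1:5000) {
    r2 <- net$activation$f(v2)
    v2n <- drop(net$W[[1]] %*% c(0.5, 0.5)) + qc[blocks[[1]]]
    v3n <- drop(net$W[[2]] %*% r2) + qc[blocks[[2]]]
    v2 <- 0.9 * v2 + 0.1 * v2n
    v3 <- 0.9 * v3 + 0.1 * v3n
  }
  Tn <- n_steps(traj)
  expect_equal(traj$v[[2]][Tn, ], v2, tolerance = 1e-5)
  expect_equal(traj$v[[3]][Tn, ], v3, tolerance = 1e-5)
})

test_that("a duration of one dt performs exactly one Euler step", {
  net <- make_net(c(1, 2), seed = 2)
  x <- 0.7
  traj <- integrate_dynamics(net, x, duration = 0.01, dt = 0.01)
  drive <- drop(net$W[[1]] %*% x)
  expect_equal(n_steps(traj), 2L)
  expect_equal(traj$v[[2]][2, ], 0 + 0.01 * (-0 + drive))
})

test_that("potentials decay monotonically with zero drive and noise", {
  net <- layered_network(c(1, 3), activation = "linear", seed = 1)
  net$W[[1]][] <- 0
  traj <- integrate_dynamics(net, 0, duration = 2, dt = 0.05,
                             v0 = list(NULL, c(1, -2, 0.5)))
  nrm <- sqrt(rowSums(traj$v[[2]]^2))
  expect_true(all(diff(nrm) < 0))
})

test_that("halving dt halves the Euler error (order-1 consistency)", {
  net <- layered_network(c(1, 1), activation = "linear", seed = 1)
  net$W[[1]][] <- 1
  x <- 1  # v(t) = 1 - exp(-t)
  exact <- 1 - exp(-1)
  err <- sapply(c(0.02, 0.01), function(dt) {
    traj <- integrate_dynamics(net, x, duration = 1, dt = dt)
    abs(traj$v[[2]][n_steps(traj), ] - exact)
  })
  ratio <- err[1] / err[2]
  expect_gt(ratio, 2 / 4)       # within factor 4 of the linear slope 2
  expect_lt(ratio, 2 * 4)
})

test_that("identical seeds give bitwise-identical noisy trajectories", {
  net <- make_net(c(2, 4, 2), seed = 5)
  t1 <- integrate_dynamics(net, c(0.2, 0.9), noise_sd = 0.3, duration = 1,
                           dt = 0.01, seed = 42)
  t2 <- integrate_dynamics(net, c(0.2, 0.9), noise_sd = 0.3, duration = 1,
                           dt = 0.01, seed = 42)
  expect_identical(t1$v, t2$v)
  expect_identical(t1$r, t2$r)
  t3 <- integrate_dynamics(net, c(0.2, 0.9), noise_sd = 0.3, duration = 1,
                           dt = 0.01, seed = 43)
  expect_false(identical(t1$v, t3$v))
})

test_that("shape mismatches and divergence raise informative errors", {
  net <- make_net(c(2, 3), seed = 1)
  expect_error(feedforward_pass(net, c(1, 2, 3)), "input layer has 2 neurons")
  expect_error(integrate_dynamics(net, c(1, 2, 3), duration = 1), "2 neurons")
  expect_error(
    integrate_dynamics(net, c(0.5, 0.5),
                       feedback = function(step, rates) rep(1e8, 3),
                       duration = 1, dt = 0.01),
    "diverged at step")
})

test_that("trajectories round-trip to a flat CSV layout", {
  net <- make_net(c(2, 2), seed = 1)
  traj <- integrate_dynamics(net, c(0.1, 0.9), duration = 0.1, dt = 0.01)
  df <- as.data.frame(traj)
  expect_equal(nrow(df), n_steps(traj))
  expect_true(all(c("t", "v_2_1", "r_1_1", "r_2_2", "c_1") %in% names(df)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  back <- utils::read.csv(path)
  expect_equal(back$r_2_1, traj$r[[2]][, 1])
})

test_that("rates always equal the activation of the potentials", {
  net <- make_net(c(2, 3, 2), seed = 9)
  traj <- integrate_dynamics(net, c(0.4, 0.6), noise_sd = 0.2, duration = 0.5,
                             dt = 0.01, seed = 1)
  for (l in 2:3) {
    expect_equal(traj$r[[l]], net$activation$f(traj$v[[l]]))
  }
})
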