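test_that("controller emits zero for zero error and stays at rest", {
  st <- controller_state(2, k = 0.5, alpha = 1)
  out <- controller_step(st, c(0, 0), dt = 0.01)
  expect_equal(out$c, c(0, 0))
  expect_equal(out$state$c_int, c(0, 0))
})

test_that("constant error drives c_int to e/alpha and c to e/alpha + k e", {
  st <- controller_state(1, k = 1, alpha = 2, tau_u = 1)
  for (i in 1:4000) st <- controller_step(st, 0.3, 0.01)$state
  expect_equal(st$c_int, 0.15, tolerance = 1e-6)
  expect_equal(controller_step(st, 0.3, 0.01)$c, 0.45, tolerance = 1e-6)
})

test_that("c_int converges to e/alpha for random errors and gains", {
  set.seed(1)
  for (i in 1:5) {
    e <- rnorm(3)
    alpha <- runif(1, 0.1, 3)
    st <- controller_state(3, k = 0, alpha = alpha, tau_u = 0.5)
    for (s in 1:6000) st <- controller_step(st, e, 0.005)$state
    expect_equal(st$c_int, e / alpha, tolerance = 1e-6)
  }
})

test_that("with k = 0 and huge tau_u the controller is purely integral", {
  st <- controller_state(1, k = 0, alpha = 1, tau_u = 1e9)
  st$c_int <- 0.7
  out <- controller_step(st, 0.5, 0.01)
  expect_equal(out$c, 0.7)                       # no proportional path
  expect_equal(out$state$c_int, 0.7, tolerance = 1e-9)
})

test_that("a disabled controller reproduces the open-loop trajectory", {
  net <- make_net(c(2, 3, 2), seed = 4)
  x <- c(0.3, 0.7)
  ff <- feedforward_pass(net, x)
  ctrl <- controller_state(2, k = 0, alpha = 1, tau_u = 1e12)
  closed <- run_closed_loop(net, x, c(0.9, 0.1), ctrl, duration = 1, dt = 0.01)
  open <- integrate_dynamics(net, x, duration = 1, dt = 0.01,
                             v0 = ff$potentials)
  for (l in 2:3) expect_equal(closed$v[[l]], open$v[[l]], tolerance = 1e-8)
})

test_that("a target equal to the open-loop output needs no feedback", {
  net <- make_net(c(2, 3, 2), seed = 4)
  x <- c(0.3, 0.7)
  y <- feedforward_pass(net, x)$rates[[3]]
  traj <- run_closed_loop(net, x, y, duration = 2, dt = 0.01)
  expect_equal(max(abs(traj$c)), 0)
  expect_equal(feedback_cost(traj), 0)
})

test_that("closed-loop control reduces the terminal output error", {
  # linear one-hidden-layer network with feedback aligned to the
  # forward influence (Q = J^T)
  net <- layered_network(c(1, 2, 1), activation = "linear", seed = 2)
  net$W[[1]][] <- c(0.6, -0.4)
  net$W[[2]][] <- c(0.5, 0.3)
  J <- cbind(net$W[[2]], 1)           # d r_out / d v_(hidden, out)
  net$Q <- t(J)
  x <- 1
  y <- feedforward_pass(net, x)$rates[[3]] + 0.5   # reachable shifted target
  traj <- run_closed_loop(net, x, y, controller_state(1, k = 0.5, alpha = 0.05),
                          duration = 5, dt = 0.01)
  e0 <- abs(traj$e[1, ])
  eT <- abs(traj$e[n_steps(traj), ])
  expect_lt(eT, e0)
  expect_lt(eT, 0.05)
})

test_that("learning separates weights so less feedback is needed", {
  trained <- layered_network(c(2, 1), seed = 1)
  trained$W[[1]][] <- c(-3, 3); trained$Q <- matrix(1)
  naive <- trained; naive$W[[1]][] <- c(0.5, 0.5)
  x <- c(0.2, 0.8)                     # B-type stimulus, target high
  e_end <- function(net) {
    tr <- run_closed_loop(net, x, 0.95, controller_state(1), duration = 10,
                          dt = 0.01)
    abs(tr$e[n_steps(tr), ])
  }
  expect_lt(e_end(trained), e_end(naive))
})

test_that("feedback weights decay geometrically without drive", {
  # zero weights and zero input: v = 0 and e = 0 throughout, so only
  # the -beta Q decay term acts
  net <- layered_network(c(1, 1), seed = 1)
  net$W[[1]][] <- 0
  Q0 <- matrix(2)
  net$Q <- Q0
  cfg <- feedback_training_config(beta = 0.1, noise_sd = 0, lr_q = 2,
                                  n_steps = 500, duration = 5, dt = 0.01,
                                  seed = 1)
  out <- train_feedback_weights(net, matrix(0, 1, 1), cfg, normalize = FALSE)
  expect_equal(out$Q[1, 1], 2 * (1 - 2 * 0.01 * 0.1)^500, tolerance = 1e-12)
})

test_that("a zero learning step leaves Q unchanged", {
  net <- make_net(c(2, 3, 2), seed = 6)
  cfg <- feedback_training_config(lr_q = 0, n_steps = 200, seed = 1)
  out <- train_feedback_weights(net, matrix(c(0.2, 0.8), 1), cfg)
  expect_identical(out$Q, net$Q)
})

test_that("feedback weights stay bounded during anti-Hebbian training", {
  net <- make_net(c(2, 4, 2), seed = 8)
  cfg <- feedback_training_config(n_steps = 3000, seed = 3)
  out <- train_feedback_weights(net, matrix(c(0.2, 0.8, 0.7, 0.3), 2,
                                            byrow = TRUE), cfg,
                                normalize = FALSE)
  expect_true(all(abs(out$Q) < 1e3))
  expect_true(all(is.finite(out$Q)))
})

test_that("feedback weights survive a CSV round trip", {
  net <- make_net(c(2, 3, 2), seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  save_feedback_weights(net, path)
  net2 <- net
  net2$Q <- matrix(0, nrow(net$Q), ncol(net$Q))
  net2 <- load_feedback_weights(net2, path)
  expect_equal(net2$Q, net$Q, tolerance = 1e-12)
  bad <- layered_network(c(2, 5, 2), seed = 1)
  expect_error(load_feedback_weights(bad, path), "layer sizes")
})
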