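test_that("constant postsynaptic rates give a zero DH update", {
  traj <- make_traj(list(cbind(runif(5)), matrix(0.4, 5, 2)))
  us <- dh_update(traj, NULL)
  expect_equal(us$deltas[[1]], matrix(0, 2, 1))
})

test_that("with constant presynaptic input DH telescopes to the delta rule", {
  traj <- make_traj(list(cbind(rep(1, 3)), cbind(c(0.2, 0.5, 0.9))))
  us <- dh_update(traj, NULL)
  expect_equal(us$deltas[[1]][1, 1], 0.7, tolerance = 1e-12)
  expect_equal(us$deltas[[1]], delta_update(traj, NULL)$deltas[[1]],
               tolerance = 1e-12)

  # multi-neuron random case, presynaptic rates constant in time
  set.seed(3)
  pre <- matrix(rep(runif(3), each = 20), 20, 3)
  post <- matrix(runif(60), 20, 3)
  traj2 <- make_traj(list(pre, post))
  expect_equal(dh_update(traj2, NULL)$deltas[[1]],
               delta_update(traj2, NULL)$deltas[[1]], tolerance = 1e-12)
})

test_that("the DH update decomposes into delta part minus pre-gap term", {
  # Dw(DH) = r_pre(T) * sum dr_post - sum (r_pre(T) - r_pre(t)) dr_post(t)
  set.seed(4)
  pre <- matrix(runif(40), 20, 2)
  post <- matrix(runif(60), 20, 3)
  traj <- make_traj(list(pre, post))
  dh <- dh_update(traj, NULL)$deltas[[1]]
  Tn <- 20
  dr <- post[-1, ] - post[-Tn, ]
  pre_T <- pre[Tn, ]
  delta_part <- tcrossprod(colSums(dr), pre_T)
  gap <- sweep(-pre[-Tn, , drop = FALSE], 2, pre_T, "+")  # r_pre(T) - r_pre(t)
  gap_part <- crossprod(dr, gap)
  expect_equal(dh - (delta_part - gap_part), matrix(0, 3, 2),
               tolerance = 1e-12)
})

test_that("delta rule evaluates its closed form directly", {
  traj <- make_traj(list(cbind(c(0.1, 0.8)), cbind(c(0.3, 0.7))))
  expect_equal(delta_update(traj, NULL)$deltas[[1]][1, 1], 0.8 * 0.4,
               tolerance = 1e-12)
  flat <- make_traj(list(cbind(c(0.1, 0.8)), cbind(c(0.3, 0.3))))
  expect_equal(delta_update(flat, NULL)$deltas[[1]][1, 1], 0)
})

test_that("monotone rate changes give sign-correct DH updates", {
  up <- make_traj(list(cbind(rep(0.6, 10)), cbind(seq(0.2, 0.9, length.out = 10))))
  dn <- make_traj(list(cbind(rep(0.6, 10)), cbind(seq(0.9, 0.2, length.out = 10))))
  expect_gt(dh_update(up, NULL)$deltas[[1]][1, 1], 0)   # potentiation
  expect_lt(dh_update(dn, NULL)$deltas[[1]][1, 1], 0)   # depression
})

test_that("online accumulation equals the batch DH computation exactly", {
  sp <- make_spiking_traj(seed = 11, duration = 1)
  a <- dh_update(sp$traj, sp$net)
  b <- dh_update(sp$traj, sp$net, online = TRUE)
  for (l in seq_along(a$deltas)) expect_equal(a$deltas[[l]], b$deltas[[l]])
})

test_that("single-step trajectories are rejected", {
  traj <- make_traj(list(cbind(0.5), cbind(0.5)))
  expect_error(dh_update(traj, NULL), "at least 2 steps")
  expect_error(delta_update(traj, NULL), "at least 2 steps")
})

test_that("backprop reference matches finite differences and closed forms", {
  net <- make_net(c(3, 4, 2), seed = 5)
  x <- c(0.2, 0.9, 0.4)
  y <- c(0.8, 0.1)
  us <- bp_update(net, x, y)
  loss <- function(net) {
    out <- feedforward_pass(net, x)$rates[[3]]
    0.5 * sum((y - out)^2)
  }
  h <- 1e-6
  for (l in 1:2) {
    fd <- net$W[[l]]
    for (i in seq_along(fd)) {
      np <- net; np$W[[l]][i] <- np$W[[l]][i] + h
      nm <- net; nm$W[[l]][i] <- nm$W[[l]][i] - h
      fd[i] <- (loss(np) - loss(nm)) / (2 * h)
    }
    expect_equal(us$deltas[[l]], -fd, tolerance = 1e-5)
  }

  # zero gradient at the optimum
  y_star <- feedforward_pass(net, x)$rates[[3]]
  z <- bp_update(net, x, y_star)
  expect_equal(max(abs(unlist(z$deltas))), 0)

  # one-layer linear net: Dw = (y - y_hat) x^T
  lin <- layered_network(c(2, 1), activation = "linear", seed = 1)
  lin$W[[1]][] <- c(0.3, -0.2)
  xl <- c(1, 2); yl <- 0.5
  yhat <- drop(lin$W[[1]] %*% xl)
  expect_equal(bp_update(lin, xl, yl)$deltas[[1]],
               (yl - yhat) * matrix(xl, 1), tolerance = 1e-12)
})

test_that("update correlation recovers exact, null and noisy relations", {
  a <- update_set(list(matrix(c(1, -2, 3, 0.5), 2)), "DH")
  expect_equal(update_correlation(a, 2 * a), 1)
  b <- update_set(list(matrix(c(1, -1, -1, 1), 2)), "BP")
  a0 <- update_set(list(matrix(c(1, 2, 3, 4), 2)), "DH")   # cov(a0, b) = 0
  expect_equal(update_correlation(a0, b), 0)
  const <- update_set(list(matrix(1, 2, 2)), "BP")
  expect_error(update_correlation(a, const), "zero-variance")

  # matched-variance noise gives R^2 about 1/2
  set.seed(10)
  r2 <- replicate(100, {
    v <- rnorm(200)
    w <- v + rnorm(200, sd = sd(v))
    ua <- update_set(list(matrix(v, 10)), "DH")
    ub <- update_set(list(matrix(w, 10)), "BP")
    update_correlation(ua, ub)
  })
  expect_equal(mean(r2), 0.5, tolerance = 0.1)
})

test_that("update sets support scaling, export and application", {
  net <- make_net(c(2, 3), seed = 2)
  traj <- integrate_dynamics(net, c(0.2, 0.8), duration = 0.5, dt = 0.01)
  us <- dh_update(traj, net)
  doubled <- us * 2
  expect_equal(doubled$deltas[[1]], 2 * us$deltas[[1]])
  expect_equal(update_slope(us, doubled), 2, tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".csv")
  write_update_csv(us, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 6)
  expect_equal(back$dw[back$post == 2 & back$pre == 1], us$deltas[[1]][2, 1])

  net2 <- apply_updates(net, us, lr = 0.5)
  expect_equal(net2$W[[1]], net$W[[1]] + 0.5 * us$deltas[[1]])
})
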