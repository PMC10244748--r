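test_that("degenerate rates give empty or saturated spike trains", {
  zero <- make_traj(list(cbind(rep(0, 50)), cbind(rep(0, 50))), dt = 0.01)
  st <- rates_to_poisson_spikes(zero, seed = 1)
  expect_equal(lengths(st$trains[[1]]), 0L)
  expect_equal(lengths(st$trains[[2]]), 0L)

  one <- make_traj(list(cbind(rep(1, 50)), cbind(rep(1, 50))), dt = 0.01)
  st1 <- rates_to_poisson_spikes(one, seed = 1)
  expect_equal(st1$trains[[2]][[1]], one$times)   # a spike in every bin
})

test_that("spike counts follow the binomial mean and spread", {
  traj <- make_traj(list(cbind(rep(0.5, 1e4)), cbind(rep(0.5, 1e4))), dt = 0.01)
  st <- rates_to_poisson_spikes(traj, seed = 7)
  count <- length(st$trains[[2]][[1]])
  expect_lt(abs(count - 5000), 3 * sqrt(1e4 * 0.25))
  expect_true(all(diff(st$trains[[2]][[1]]) > 0))
})

test_that("rates outside [0, 1] are rejected with location info", {
  bad <- make_traj(list(cbind(c(0.5, 1.2)), cbind(c(0.5, 0.5))), dt = 0.01)
  expect_error(rates_to_poisson_spikes(bad, seed = 1),
               "outside \\[0,1\\] at layer 1, neuron 1, step 2")
})

test_that("pairwise STDP evaluates the exponential kernel exactly", {
  k <- stdp_kernel(a_plus = 0.01, a_minus = 0.012, tau_plus = 0.02,
                   tau_minus = 0.02)
  expect_equal(stdp_pairwise_update(0.010, 0.015, k), 0.01 * exp(-0.25),
               tolerance = 1e-12)
  expect_equal(stdp_pairwise_update(0.015, 0.010, k), -0.012 * exp(-0.25),
               tolerance = 1e-12)
  expect_equal(stdp_pairwise_update(numeric(0), 0.01, k), 0)
  expect_equal(stdp_pairwise_update(0.01, numeric(0), k), 0)
  expect_error(stdp_pairwise_update(c(2, 1), 1.5, k), "sorted")
})

test_that("all-to-all sums every in-window pair; pairs beyond 5 tau drop", {
  k <- stdp_kernel(a_plus = 0.01, a_minus = 0.01, tau_plus = 0.02,
                   tau_minus = 0.02)
  # two pre, one post: both pre before post
  dw <- stdp_pairwise_update(c(0.01, 0.02), 0.03, k)
  expect_equal(dw, 0.01 * (exp(-0.02 / 0.02) + exp(-0.01 / 0.02)),
               tolerance = 1e-12)
  # pair separated by more than window * tau contributes nothing
  expect_equal(stdp_pairwise_update(0, 0.11, k), 0)
})

test_that("nearest-neighbor pairing uses only the closest partners", {
  k <- stdp_kernel(a_plus = 0.01, a_minus = 0, tau_plus = 0.02,
                   tau_minus = 0.02, pairing = "nearest_neighbor")
  # two pre spikes before one post: only the nearest (0.02) pairs
  expect_equal(stdp_pairwise_update(c(0.01, 0.02), 0.03, k),
               0.01 * exp(-0.01 / 0.02), tolerance = 1e-12)
})

test_that("expected update with one realization equals a seeded pairwise run", {
  sp <- make_spiking_traj(seed = 21, sizes = c(2, 3, 2), duration = 1)
  k <- stdp_kernel()
  eu <- stdp_expected_update(sp$traj, sp$net, k, n_realizations = 1, seed = 99)
  st <- rates_to_poisson_spikes(sp$traj, seed = 99)
  for (l in 2:3) {
    for (post in seq_len(sp$net$layer_sizes[l])) {
      for (pre in seq_len(sp$net$layer_sizes[l - 1])) {
        ref <- stdp_pairwise_update(st$trains[[l - 1]][[pre]],
                                    st$trains[[l]][[post]], k)
        expect_equal(eu$deltas[[l - 1]][post, pre], ref, tolerance = 1e-10)
      }
    }
  }
})

test_that("expected updates are deterministic under a seed", {
  sp <- make_spiking_traj(seed = 22, sizes = c(1, 2), duration = 1)
  a <- stdp_expected_update(sp$traj, sp$net, n_realizations = 3, seed = 5)
  b <- stdp_expected_update(sp$traj, sp$net, n_realizations = 3, seed = 5)
  expect_identical(a$deltas, b$deltas)
})

test_that("balanced kernels have zero expected update for constant rates", {
  traj <- make_traj(list(cbind(rep(0.5, 300)), cbind(rep(0.4, 300))),
                    dt = 0.01)
  k <- stdp_kernel(a_plus = 0.01, a_minus = 0.01, tau_plus = 0.05,
                   tau_minus = 0.05)
  net <- layered_network(c(1, 1), seed = 1)
  n <- 500
  draws <- vapply(seq_len(n), function(i) {
    stdp_expected_update(traj, net, k, 1, seed = 1000 + i)$deltas[[1]][1, 1]
  }, 0)
  sem <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws)), 3 * sem)
})

test_that("updates of time-disjoint trajectories add (all-to-all window)", {
  set.seed(30)
  r1 <- 0.1 + 0.8 * (1 + sin(seq(0, 4, length.out = 150))) / 2
  r2 <- 0.1 + 0.8 * (1 + cos(seq(0, 4, length.out = 150))) / 2
  gap <- rep(0, 120)                     # longer than the pairing window
  k <- stdp_kernel(tau_plus = 0.1, tau_minus = 0.1)
  net <- layered_network(c(1, 1), seed = 1)
  z <- numeric(150)
  mk <- function(pre, post) make_traj(list(cbind(pre), cbind(post)), dt = 0.01)
  joint <- mk(c(r1, gap, r2), c(rev(r1), gap, rev(r2)))
  # with a shared seed the uniform draws align bin by bin, so the part
  # trajectories produce exactly the joint trajectory's spikes in their
  # own window and none elsewhere; the window truncation removes every
  # cross-gap pair, and the sums match exactly
  nr <- 20
  ej <- stdp_expected_update(joint, net, k, nr, seed = 1)$deltas[[1]][1, 1]
  e1 <- stdp_expected_update(mk(c(r1, gap, z), c(rev(r1), gap, z)), net, k,
                             nr, seed = 1)$deltas[[1]][1, 1]
  e2 <- stdp_expected_update(mk(c(z, gap, r2), c(z, gap, rev(r2))), net, k,
                             nr, seed = 1)$deltas[[1]][1, 1]
  expect_equal(ej, e1 + e2, tolerance = 1e-10)
})

test_that("averaging realizations tightens the alignment with the DH update", {
  sp <- make_spiking_traj(seed = 23, sizes = c(2, 6, 4), duration = 2)
  dh <- dh_update(sp$traj, sp$net)
  r2_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) update_correlation(dh,
      stdp_expected_update(sp$traj, sp$net, n_realizations = n,
                           seed = 37 * s)), 0))
  }
  r2_few <- r2_at(1, 1:5)
  r2_many <- r2_at(100, 1:3)
  expect_gt(r2_many, r2_few)
  expect_gt(r2_many, 0.3)
})
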