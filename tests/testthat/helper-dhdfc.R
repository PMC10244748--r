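# Build a trajectory object directly from per-layer rate matrices, for
# plasticity/loss tests that need hand-crafted rate patterns.
make_traj <- function(r_layers, dt = 1, c_mat = NULL, e_mat = NULL) {
  r <- lapply(r_layers, function(m) {
    if (is.null(dim(m))) matrix(m, ncol = 1) else as.matrix(m)
  })
  Tn <- nrow(r[[1L]])
  stopifnot(all(vapply(r, nrow, 1L) == Tn))
  dhdfc:::new_trajectory(
    times = seq(0, by = dt, length.out = Tn),
    dt = dt,
    layer_sizes = vapply(r, ncol, 1L),
    r = r,
    v = vector("list", length(r)),
    c = c_mat, e = e_mat
  )
}

# Small random network with weights scaled to keep rates away from
# saturation.
make_net <- function(sizes, seed = 1, activation = "sigmoid", w_sd = 0.8) {
  layered_network(sizes, activation = activation, seed = seed, w_sd = w_sd)
}

# A smooth closed-loop trajectory with all rates (including the clamped
# input) in [0, 1], suitable for Poisson spike conversion.
make_spiking_traj <- function(seed = 1, sizes = c(2, 6, 4), duration = 3,
                              dt = 0.01) {
  set.seed(seed)
  net <- make_net(sizes, seed = seed)
  x <- runif(sizes[1], 0.2, 0.8)
  y <- runif(sizes[length(sizes)], 0.1, 0.9)
  traj <- run_closed_loop(net, x, y, duration = duration, dt = dt)
  list(net = net, traj = traj)
}
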