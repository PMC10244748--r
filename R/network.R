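#' Construct a layered rate network
#'
#' A feedforward network of leaky rate neurons.  Neuron potentials in
#' layer \eqn{l+1} are driven by `W[[l]] %*% r_l` where `r_l` are the
#' rates of layer \eqn{l}; input-layer neurons are clamped to the
#' stimulus and have no dynamics.  A single feedback matrix `Q` maps the
#' controller signal (one channel per output neuron) onto every
#' non-input neuron, so apical feedback can steer the whole hierarchy.
#'
#' Feedforward weights are initialised i.i.d. Gaussian with standard
#' deviation \eqn{1/\sqrt{fan_{in}}}; feedback weights with
#' \eqn{1/\sqrt{n_{out}}} and are usually replaced by
#' [train_feedback_weights()] before learning.
#'
#' @param layer_sizes Integer vector (input, hidden..., output), all positive.
#' @param activation Activation name or `dhdfc_activation` object.
#' @param seed Optional integer seed for weight initialisation.
#' @param w_sd,q_sd Optional scalar standard deviations overriding the
#'   fan-in scaling.
#' @return An object of class `dhdfc_network` with elements
#'   `layer_sizes`, `W` (list, `W[[l]]` is `layer_sizes[l+1] x
#'   layer_sizes[l]`), `Q` (`sum(layer_sizes[-1]) x n_out`) and
#'   `activation`.
#' @examples
#' net <- layered_network(c(2, 4, 2), seed = 1)
#' sapply(net$W, dim)
#' @export
layered_network <- function(layer_sizes, activation = "sigmoid", seed = NULL,
                            w_sd = NULL, q_sd = NULL) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes must be at least two positive integers", call. = FALSE)
  }
  if (is.character(activation)) activation <- activation_fn(activation)
  stopifnot(inherits(activation, "dhdfc_activation"))
  if (!is.null(seed)) set.seed(seed)
  n_layers <- length(layer_sizes)
  n_out <- layer_sizes[n_layers]
  W <- vector("list", n_layers - 1L)
  for (l in seq_len(n_layers - 1L)) {
    sd_l <- if (is.null(w_sd)) 1 / sqrt(layer_sizes[l]) else w_sd
    W[[l]] <- matrix(stats::rnorm(layer_sizes[l + 1L] * layer_sizes[l], 0, sd_l),
                     nrow = layer_sizes[l + 1L], ncol = layer_sizes[l])
  }
  n_units <- sum(layer_sizes[-1L])
  sd_q <- if (is.null(q_sd)) 1 / sqrt(n_out) else q_sd
  Q <- matrix(stats::rnorm(n_units * n_out, 0, sd_q), nrow = n_units, ncol = n_out)
  net <- structure(list(layer_sizes = layer_sizes, W = W, Q = Q,
                        activation = activation),
                   class = "dhdfc_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  ls <- net$layer_sizes
  L <- length(ls)
  for (l in seq_len(L - 1L)) {
    d <- dim(net$W[[l]])
    if (d[1] != ls[l + 1L] || d[2] != ls[l]) {
      stop(sprintf("W[[%d]] has shape %dx%d, expected %dx%d",
                   l, d[1], d[2], ls[l + 1L], ls[l]), call. = FALSE)
    }
    if (!all(is.finite(net$W[[l]]))) stop("non-finite feedforward weights",
                                          call. = FALSE)
  }
  if (nrow(net$Q) != sum(ls[-1L]) || ncol(net$Q) != ls[L]) {
    stop(sprintf("Q has shape %dx%d, expected %dx%d", nrow(net$Q), ncol(net$Q),
                 sum(ls[-1L]), ls[L]), call. = FALSE)
  }
  if (!all(is.finite(net$Q))) stop("non-finite feedback weights", call. = FALSE)
  invisible(net)
}

#' @export
print.dhdfc_network <- function(x, ...) {
  cat("<dhdfc_network ", paste(x$layer_sizes, collapse = "-"),
      ", activation: ", x$activation$name, ">\n", sep = "")
  invisible(x)
}

# Row ranges of Q corresponding to each non-input layer (2..L).
q_row_blocks <- function(net) {
  ls <- net$layer_sizes
  ends <- cumsum(ls[-1L])
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  Map(function(s, e) s:e, starts, ends)
}

#' Open-loop feedforward pass
#'
#' Propagates a clamped input through the network with the controller
#' silent.  Because the architecture is strictly feedforward and the
#' input layer is clamped, the equilibrium of the leaky dynamics is
#' reached layer by layer: \eqn{v_l = W_{l-1} r_{l-1}}, \eqn{r_l =
#' \phi(v_l)}.
#'
#' @param net A `dhdfc_network`.
#' @param x Input vector (clamped rates), length `layer_sizes[1]`.
#' @return List with `rates` (list of per-layer rate vectors, the first
#'   being `x`) and `potentials` (list for layers 2..L).
#' @export
feedforward_pass <- function(net, x) {
  stopifnot(inherits(net, "dhdfc_network"))
  x <- as.numeric(x)
  if (length(x) != net$layer_sizes[1L]) {
    stop(sprintf("input has length %d but the input layer has %d neurons",
                 length(x), net$layer_sizes[1L]), call. = FALSE)
  }
  L <- length(net$layer_sizes)
  rates <- vector("list", L)
  potentials <- vector("list", L)
  rates[[1L]] <- x
  for (l in 2:L) {
    v <- drop(net$W[[l - 1L]] %*% rates[[l - 1L]])
    potentials[[l]] <- v
    rates[[l]] <- net$activation$f(v)
  }
  list(rates = rates, potentials = potentials)
}

new_trajectory <- function(times, dt, layer_sizes, r, v, c = NULL, e = NULL) {
  structure(list(times = times, dt = dt, layer_sizes = layer_sizes,
                 r = r, v = v, c = c, e = e),
            class = "dhdfc_trajectory")
}

#' @export
print.dhdfc_trajectory <- function(x, ...) {
  cat("<dhdfc_trajectory ", paste(x$layer_sizes, collapse = "-"),
      ", ", length(x$times), " steps, dt = ", x$dt,
      if (!is.null(x$c)) ", closed loop" else "", ">\n", sep = "")
  invisible(x)
}

#' Number of recorded time points in a trajectory
#' @param traj A `dhdfc_trajectory`.
#' @export
n_steps <- function(traj) length(traj$times)

#' Output rates of a trajectory
#' @param traj A `dhdfc_trajectory`.
#' @return Matrix (time points x output neurons).
#' @export
output_rates <- function(traj) traj$r[[length(traj$layer_sizes)]]

#' Integrate the leaky rate dynamics
#'
#' Forward-Euler integration of
#' \deqn{\dot v = -v + W r_{pre} + Q c(t) + \epsilon,\qquad r = \phi(v),}
#' with the membrane time constant fixed to 1 (time is measured in units
#' of it).  The input layer is clamped to `x`; only hidden and output
#' neurons have dynamics.  `feedback` supplies the controller signal at
#' each step; `noise_sd` adds fresh zero-mean Gaussian noise to every
#' neuron's potential derivative at every step.
#'
#' @param net A `dhdfc_network`.
#' @param x Clamped input vector.
#' @param feedback `NULL` (no feedback, `c = 0`) or a function
#'   `function(step, rates)` returning the controller vector (length =
#'   output size) for the current step; `rates` is the current list of
#'   per-layer rate vectors.
#' @param noise_sd Standard deviation of the potential noise (>= 0).
#' @param duration Total integration time (>= `dt`).
#' @param dt Euler step.
#' @param seed Optional seed; identical seeds give bitwise-identical
#'   trajectories.
#' @param v0 Optional list of initial potentials for layers 2..L
#'   (defaults to zero vectors).
#' @return A `dhdfc_trajectory` recording every step (including the
#'   initial state): per-layer rates `r`, potentials `v`, and the
#'   controller signal `c` (zeros when `feedback` is `NULL`).
#' @examples
#' net <- layered_network(c(2, 1), seed = 1, activation = "sigmoid")
#' net$W[[1]][] <- c(0.5, 0)
#' tr <- integrate_dynamics(net, c(1, 0), duration = 10, dt = 0.01)
#' tail(tr$v[[2]], 1)  # ~0.5
#' @export
integrate_dynamics <- function(net, x, feedback = NULL, noise_sd = 0,
                               duration, dt = 0.01, seed = NULL, v0 = NULL) {
  stopifnot(inherits(net, "dhdfc_network"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration < dt) stop("duration must be at least one step", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  x <- as.numeric(x)
  if (length(x) != net$layer_sizes[1L]) {
    stop(sprintf("input has length %d but the input layer has %d neurons",
                 length(x), net$layer_sizes[1L]), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  ls <- net$layer_sizes
  L <- length(ls)
  n_out <- ls[L]
  steps <- as.integer(round(duration / dt))
  times <- seq(0, by = dt, length.out = steps + 1L)
  blocks <- q_row_blocks(net)

  v <- vector("list", L)
  for (l in 2:L) {
    v[[l]] <- if (is.null(v0)) rep(0, ls[l]) else as.numeric(v0[[l]])
  }
  r <- vector("list", L)
  r[[1L]] <- x
  for (l in 2:L) r[[l]] <- net$activation$f(v[[l]])

  Rrec <- vector("list", L)
  Vrec <- vector("list", L)
  Rrec[[1L]] <- matrix(x, nrow = steps + 1L, ncol = ls[1L], byrow = TRUE)
  for (l in 2:L) {
    Rrec[[l]] <- matrix(NA_real_, steps + 1L, ls[l])
    Vrec[[l]] <- matrix(NA_real_, steps + 1L, ls[l])
    Rrec[[l]][1L, ] <- r[[l]]
    Vrec[[l]][1L, ] <- v[[l]]
  }
  Crec <- matrix(0, steps + 1L, n_out)

  zero_c <- rep(0, n_out)
  for (s in seq_len(steps)) {
    c_now <- if (is.null(feedback)) zero_c else as.numeric(feedback(s, r))
    Crec[s, ] <- c_now
    qc <- drop(net$Q %*% c_now)
    r_prev <- r  # all layers advance simultaneously from the state at time t
    for (l in 2:L) {
      drive <- drop(net$W[[l - 1L]] %*% r_prev[[l - 1L]]) + qc[blocks[[l - 1L]]]
      if (noise_sd > 0) drive <- drive + stats::rnorm(ls[l], 0, noise_sd)
      v[[l]] <- v[[l]] + dt * (-v[[l]] + drive)
      r[[l]] <- net$activation$f(v[[l]])
      if (!all(is.finite(v[[l]])) || any(abs(v[[l]]) > 1e6)) {
        stop(sprintf("dynamics diverged at step %d (layer %d)", s, l),
             call. = FALSE)
      }
      Vrec[[l]][s + 1L, ] <- v[[l]]
      Rrec[[l]][s + 1L, ] <- r[[l]]
    }
  }
  if (!is.null(feedback)) {
    Crec[steps + 1L, ] <- as.numeric(feedback(steps + 1L, r))
  }
  new_trajectory(times, dt, ls, Rrec, Vrec, c = Crec)
}

#' Convert a trajectory to a flat data frame
#'
#' One row per time step; columns `t`, then potentials `v_<layer>_<i>`,
#' rates `r_<layer>_<i>`, controller `c_<i>` and output error `e_<i>`
#' when present.
#'
#' @param x A `dhdfc_trajectory`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @export
as.data.frame.dhdfc_trajectory <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  L <- length(x$layer_sizes)
  out <- data.frame(t = x$times)
  for (l in 2:L) {
    V <- x$v[[l]]
    colnames(V) <- sprintf("v_%d_%d", l, seq_len(ncol(V)))
    out <- cbind(out, V)
  }
  for (l in seq_len(L)) {
    R <- x$r[[l]]
    colnames(R) <- sprintf("r_%d_%d", l, seq_len(ncol(R)))
    out <- cbind(out, R)
  }
  if (!is.null(x$c)) {
    C <- x$c
    colnames(C) <- sprintf("c_%d", seq_len(ncol(C)))
    out <- cbind(out, C)
  }
  if (!is.null(x$e)) {
    E <- x$e
    colnames(E) <- sprintf("e_%d", seq_len(ncol(E)))
    out <- cbind(out, E)
  }
  out
}

#' Write a trajectory to CSV
#' @param traj A `dhdfc_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
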