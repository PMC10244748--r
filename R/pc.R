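#' Supervised predictive-coding inference
#'
#' Runs the inference dynamics of a hierarchical predictive-coding
#' network built on the same weights as a `dhdfc_network`.  Layer
#' activities \eqn{x_l} carry prediction errors
#' \eqn{\epsilon_l = x_l - W_{l-1}\phi(x_{l-1})} (computed quantities,
#' not dynamical states), and free activities descend the energy
#' \eqn{E = \sum_l \lVert\epsilon_l\rVert^2/2}:
#' \deqn{x_l \leftarrow x_l + \eta\,[-\epsilon_l +
#'   \phi'(x_l)\circ(W_l^\top \epsilon_{l+1})].}
#' The input layer is always clamped to `x`.  In training mode
#' (`y_target` given) the output layer is clamped to the target and the
#' prediction errors act as implicit feedback on the hidden layers; in
#' test mode the output is free and inference settles onto the
#' feedforward pass.
#'
#' Activities are initialised at the feedforward predictions
#' \eqn{x_l = W_{l-1}\phi(x_{l-1})} (override with `x0`).  In training
#' mode the pre-clamp feedforward state is recorded as the first
#' trajectory row, so the clamp-induced jump of the output activity is
#' part of the recorded dynamics that temporal plasticity rules
#' integrate.
#'
#' @param net A `dhdfc_network` (its `Q` is ignored; prediction errors
#'   are the feedback).
#' @param x Input vector (clamped).
#' @param y_target Target output activities, or `NULL` for free-output
#'   test mode.
#' @param n_steps Number of inference steps.
#' @param step_size Inference step size \eqn{\eta}.
#' @param x0 Optional list of initial activities for layers 2..L.
#' @return An object of class `dhdfc_pc_traj`: `X` (list per layer of
#'   recorded activity matrices), `energies` (energy at each recorded
#'   state; in training mode the first entry is the pre-clamp state and
#'   the sequence from the second entry on is non-increasing for small
#'   `step_size`), `clamped_output`, `layer_sizes`.
#' @export
pc_inference <- function(net, x, y_target = NULL, n_steps = 50,
                         step_size = 0.1, x0 = NULL) {
  stopifnot(inherits(net, "dhdfc_network"), n_steps >= 1, step_size > 0)
  ls <- net$layer_sizes
  L <- length(ls)
  x <- as.numeric(x)
  if (length(x) != ls[1L]) stop("input length mismatch", call. = FALSE)
  clamped <- !is.null(y_target)
  if (clamped) {
    y_target <- as.numeric(y_target)
    if (length(y_target) != ls[L]) stop("target length mismatch", call. = FALSE)
  }
  phi <- net$activation$f
  dphi <- net$activation$grad

  act <- vector("list", L)
  act[[1L]] <- x
  for (l in 2:L) {
    act[[l]] <- if (is.null(x0)) drop(net$W[[l - 1L]] %*% phi(act[[l - 1L]])) else
      as.numeric(x0[[l]])
  }

  eps_of <- function(a) {
    lapply(2:L, function(l) a[[l]] - drop(net$W[[l - 1L]] %*% phi(a[[l - 1L]])))
  }
  energy_of <- function(eps) sum(vapply(eps, function(e) sum(e^2), 0)) / 2

  n_rec <- n_steps + 1L + as.integer(clamped)
  X <- lapply(seq_len(L), function(l) matrix(NA_real_, n_rec, ls[l]))
  energies <- numeric(n_rec)
  rec <- function(row, a, eps) {
    for (l in seq_len(L)) X[[l]][row, ] <<- a[[l]]
    energies[row] <<- energy_of(eps)
  }

  row <- 1L
  if (clamped) {
    rec(row, act, eps_of(act))         # pre-clamp feedforward state
    act[[L]] <- y_target
    row <- 2L
  }
  eps <- eps_of(act)
  rec(row, act, eps)
  free_layers <- if (clamped) (2:L)[-(L - 1L)] else 2:L
  if (L == 2L && clamped) free_layers <- integer(0)
  for (s in seq_len(n_steps)) {
    new_act <- act
    for (l in free_layers) {
      grad <- -eps[[l - 1L]]
      if (l < L) {
        grad <- grad + dphi(act[[l]]) * drop(crossprod(net$W[[l]], eps[[l]]))
      }
      new_act[[l]] <- act[[l]] + step_size * grad
    }
    act <- new_act
    if (!all(vapply(act[-1L], function(a) all(is.finite(a)), TRUE))) {
      stop("predictive-coding inference diverged; reduce step_size",
           call. = FALSE)
    }
    eps <- eps_of(act)
    row <- row + 1L
    rec(row, act, eps)
  }
  structure(list(X = X, energies = energies, clamped_output = clamped,
                 layer_sizes = ls, activation = net$activation),
            class = "dhdfc_pc_traj")
}

#' @export
print.dhdfc_pc_traj <- function(x, ...) {
  cat("<pc inference trajectory, ", nrow(x$X[[1L]]), " states, final energy ",
      signif(utils::tail(x$energies, 1L), 4), ">\n", sep = "")
  invisible(x)
}

#' Differential Hebbian update along a predictive-coding trajectory
#'
#' Applies the temporal rule with \eqn{r_{pre} = \phi(x_{l-1}(t))} and
#' \eqn{r_{post} = \phi(x_l(t))} summed along the recorded inference
#' trajectory (including the output clamp transient).  A stationary
#' trajectory yields a zero update; constant presynaptic activities
#' collapse it to the delta rule on initial/final postsynaptic values.
#'
#' @param pc_traj A `dhdfc_pc_traj` from a training-mode inference.
#' @param net The generating network.
#' @return A `dhdfc_updates` with rule `"DH"`.
#' @export
pc_dh_update <- function(pc_traj, net) {
  stopifnot(inherits(pc_traj, "dhdfc_pc_traj"))
  if (nrow(pc_traj$X[[1L]]) < 2L) {
    stop("inference trajectory needs at least 2 recorded states", call. = FALSE)
  }
  phi <- pc_traj$activation$f
  L <- length(pc_traj$layer_sizes)
  Tn <- nrow(pc_traj$X[[1L]])
  deltas <- vector("list", L - 1L)
  for (l in 2:L) {
    pre <- phi(pc_traj$X[[l - 1L]])
    post <- phi(pc_traj$X[[l]])
    dpost <- post[-1L, , drop = FALSE] - post[-Tn, , drop = FALSE]
    deltas[[l - 1L]] <- crossprod(dpost, pre[-Tn, , drop = FALSE])
  }
  update_set(deltas, "DH")
}

#' Hebbian-error update at the predictive-coding equilibrium
#'
#' The standard predictive-coding weight update: prediction error times
#' presynaptic activity at the end of inference,
#' \eqn{\Delta W_{l-1} = \epsilon_l\,\phi(x_{l-1})^\top}
#' (the energy-descent direction for the weights).
#'
#' @inheritParams pc_dh_update
#' @return A `dhdfc_updates` with rule `"delta"` (it is the
#'   dendritic-error form of the PC family).
#' @export
pc_hebbian_update <- function(pc_traj, net) {
  stopifnot(inherits(pc_traj, "dhdfc_pc_traj"))
  phi <- pc_traj$activation$f
  L <- length(pc_traj$layer_sizes)
  Tn <- nrow(pc_traj$X[[1L]])
  deltas <- vector("list", L - 1L)
  for (l in 2:L) {
    x_pre <- pc_traj$X[[l - 1L]][Tn, ]
    eps_l <- pc_traj$X[[l]][Tn, ] -
      drop(net$W[[l - 1L]] %*% phi(x_pre))
    deltas[[l - 1L]] <- tcrossprod(eps_l, phi(x_pre))
  }
  update_set(deltas, "delta")
}

#' Train a predictive-coding network
#'
#' Per-sample training: clamp input and target, run inference, update
#' the weights either with the standard Hebbian-error rule at the
#' inferred equilibrium (`"hebbian_error"`) or with the differential
#' Hebbian rule integrated along the inference trajectory (`"dh"`).
#' Classification is by argmax of the feedforward output activities.
#'
#' @param net A `dhdfc_network`.
#' @param dataset List with `x` (sample matrix, rows = samples) and
#'   `targets` (target activity matrix) and optionally `labels`
#'   (integer class per sample) — the format produced by
#'   [gen_gaussian_classification()].
#' Class targets are supplied as one-hot *rates* (e.g. 0.95/0.05) for
#' consistency with the rest of the package; before clamping they are
#' mapped into activity space through the activation inverse, so the
#' clamp-induced change of the output *rate* is exactly the rate-space
#' error.  Clamping the raw rate values directly would park the output
#' activities in the saturated region of the activation, where the
#' temporal learning signal all but vanishes.
#'
#' @param rule `"hebbian_error"` or `"dh"`.
#' @param epochs Number of passes over the data.
#' @param lr Learning rate.
#' @param n_steps,step_size Inference settings.
#' @param seed Seed controlling sample order shuffling.
#' @param target_space `"rate"` (default; targets pass through the
#'   activation inverse before clamping) or `"activity"` (targets are
#'   clamped as given).
#' @return List with `net` (trained), and `metrics`, a data frame with
#'   per-epoch training error rate.
#' @export
train_pc <- function(net, dataset, rule = c("hebbian_error", "dh"),
                     epochs = 30, lr = 0.05, n_steps = 40, step_size = 0.1,
                     seed = NULL, target_space = c("rate", "activity")) {
  rule <- match.arg(rule)
  target_space <- match.arg(target_space)
  stopifnot(inherits(net, "dhdfc_network"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset$x)
  labels <- dataset$labels
  if (is.null(labels)) labels <- max.col(dataset$targets)
  targets <- as.matrix(dataset$targets)
  if (target_space == "rate") targets <- net$activation$inv(targets)
  metrics <- data.frame(epoch = seq_len(epochs), train_error = NA_real_)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      tr <- pc_inference(net, dataset$x[i, ], targets[i, ],
                         n_steps = n_steps, step_size = step_size)
      us <- if (rule == "dh") pc_dh_update(tr, net) else pc_hebbian_update(tr, net)
      if (lr != 0) net <- apply_updates(net, us, lr)
    }
    pred <- pc_predict(net, dataset$x)
    metrics$train_error[ep] <- mean(pred != labels)
  }
  list(net = net, metrics = metrics)
}

#' Feedforward predictions of a predictive-coding network
#'
#' Equivalent to free-output inference run to convergence: activities
#' take their feedforward values and the predicted class is the argmax
#' of the output activities.
#'
#' @param net A `dhdfc_network`.
#' @param x Matrix of inputs (rows = samples) or a single vector.
#' @return Integer vector of predicted class indices.
#' @export
pc_predict <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  phi <- net$activation$f
  A <- t(x)
  L <- length(net$layer_sizes)
  for (l in 2:L) A <- net$W[[l - 1L]] %*% phi(A)
  max.col(t(A))
}
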