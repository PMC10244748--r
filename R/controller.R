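#' Proportional-integral controller state
#'
#' The global controller that computes the apical feedback signal.  At
#' every step it emits \eqn{c(t) = c_{int}(t) + k\,e(t)} where
#' \eqn{e(t)} is the output error (target rate minus current output
#' rate), and the integral term follows the leaky dynamics
#' \eqn{\tau_u \dot c_{int} = e/\alpha - c_{int}}.  The leak constant
#' \eqn{\alpha} only scales the integral path, exactly as the control
#' law is written.
#'
#' The default `alpha = 0.02` gives the integral path a DC gain of 50.
#' Feedback in this framework is *strong*: it must actually hold the
#' output at its target, and near the saturated one-hot levels
#' (0.95/0.05) the sigmoid slope is about 0.05, so a loop gain of
#' order `phi' / alpha` of a few is needed for the controller to pull
#' the output inside the target tolerance even before any learning.
#'
#' @param n_out Number of output neurons (controller channels).
#' @param k Proportional gain (>= 0), dimensionless.  Default 0.5.
#' @param alpha Integral leak constant (> 0).  Default 0.02 (see
#'   Details).
#' @param tau_u Integral time constant (> 0), in units of the membrane
#'   time constant.  Default 1.
#' @return An object of class `dhdfc_controller`.
#' @export
controller_state <- function(n_out, k = 0.5, alpha = 0.02, tau_u = 1) {
  stopifnot(k >= 0, alpha > 0, tau_u > 0, n_out >= 1)
  structure(list(c_int = rep(0, n_out), k = k, alpha = alpha, tau_u = tau_u),
            class = "dhdfc_controller")
}

#' One controller update
#'
#' @param state A `dhdfc_controller`.
#' @param e Output-error vector (target minus current output rate).
#' @param dt Time step (> 0).
#' @return List with `c`, the emitted control vector for the current
#'   step, and `state`, the controller with its integral term advanced
#'   by one Euler step.
#' @examples
#' st <- controller_state(1, k = 1, alpha = 2)
#' controller_step(st, e = 0.3, dt = 0.01)$c
#' @export
controller_step <- function(state, e, dt) {
  stopifnot(inherits(state, "dhdfc_controller"), dt > 0)
  e <- as.numeric(e)
  if (!all(is.finite(e))) {
    stop("non-finite output error reached the controller", call. = FALSE)
  }
  c_out <- state$c_int + state$k * e
  state$c_int <- state$c_int + (dt / state$tau_u) * (e / state$alpha - state$c_int)
  list(c = c_out, state = state)
}

#' Closed-loop simulation of network plus controller
#'
#' Simulates one stimulus presentation with the PI controller active.
#' The network starts at its open-loop equilibrium for `x` (the settled
#' response before any feedback acts), the controller integral term is
#' reset to zero at stimulus onset, and at every step the error
#' \eqn{e(t) = y^* - r_{out}(t)} is fed to the controller whose output
#' is mapped through `Q` into every non-input neuron.
#'
#' @param net A `dhdfc_network`.
#' @param x Clamped input vector.
#' @param y_target Target output rates (within the activation range).
#' @param ctrl A `dhdfc_controller`; defaults to `controller_state()`
#'   with package defaults.
#' @param duration,dt Integration horizon and step.
#' @param noise_sd Potential noise standard deviation.
#' @param seed Optional seed.
#' @return A `dhdfc_trajectory` with `c` and `e` recorded at every step.
#' @export
run_closed_loop <- function(net, x, y_target, ctrl = NULL,
                            duration = 3, dt = 0.01, noise_sd = 0,
                            seed = NULL) {
  stopifnot(inherits(net, "dhdfc_network"))
  n_out <- net$layer_sizes[length(net$layer_sizes)]
  y_target <- as.numeric(y_target)
  if (length(y_target) != n_out) {
    stop(sprintf("y_target has length %d but the output layer has %d neurons",
                 length(y_target), n_out), call. = FALSE)
  }
  if (is.null(ctrl)) ctrl <- controller_state(n_out)
  L <- length(net$layer_sizes)
  ff <- feedforward_pass(net, x)

  env <- new.env(parent = emptyenv())
  env$ctrl <- ctrl
  env$e <- matrix(NA_real_, as.integer(round(duration / dt)) + 1L, n_out)
  fb <- function(step, rates) {
    e <- y_target - rates[[L]]
    env$e[step, ] <- e
    st <- controller_step(env$ctrl, e, dt)
    env$ctrl <- st$state
    st$c
  }
  traj <- withCallingHandlers(
    integrate_dynamics(net, x, feedback = fb, noise_sd = noise_sd,
                       duration = duration, dt = dt, seed = seed,
                       v0 = ff$potentials),
    error = function(err) {
      if (grepl("diverged", conditionMessage(err))) {
        stop("closed-loop simulation became unstable (", conditionMessage(err),
             "); consider a smaller proportional gain k or a smaller dt",
             call. = FALSE)
      }
    }
  )
  traj$e <- env$e
  traj
}

#' Anti-Hebbian pre-training of the feedback weights
#'
#' Learns the feedback matrix `Q` before any feedforward learning, with
#' the feedforward weights frozen.  For each training input the network
#' is simulated in closed loop around its own noise-free output (so the
#' error is driven purely by injected potential noise), and at every
#' step `Q` follows the anti-Hebbian rule
#' \deqn{\Delta Q = \eta\,dt\,(-v\,c^\top - \beta Q),}
#' where \eqn{v} stacks the potentials of all non-input neurons,
#' measured relative to their noise-free equilibrium for the current
#' stimulus (the DC component of the potential carries no information
#' about forward influence and would otherwise bury the learning
#' signal; what the rule must correlate are the noise *fluctuations*
#' that propagate to the output).  Noise injected into a neuron
#' propagates forward, the controller reacts, and the resulting
#' (negative) fluctuation-control correlation aligns each neuron's
#' feedback weights with its forward influence on the output.
#'
#' During this phase the loop runs, by default, with a weak
#' proportional-only controller (`k = 1`, negligible integral path;
#' override with `cfg$ctrl`).  Two reasons: the initial `Q` is random,
#' so a strong integral gain could destabilise the loop before any
#' alignment has been learned; and the integral term is a low-passed
#' copy of the error whose lag decorrelates the control signal from
#' the instantaneous potential fluctuations that carry the alignment
#' information.
#'
#' Because the correlation amplitude scales with the (small) stationary
#' noise variance, the learned `Q` is returned rescaled by a single
#' global factor so that its mean column norm is 1: anti-Hebbian
#' learning fixes the feedback *directions* (and the relative gains of
#' the error channels, which a per-column rescaling would distort),
#' while the overall loop gain is set by the controller constants.
#' Set `normalize = FALSE` to keep the raw magnitudes.
#'
#' @param net A `dhdfc_network` (its `W` is not modified).
#' @param inputs Matrix of training inputs (rows) or list of input
#'   vectors; cycled over during training.
#' @param cfg List with elements `beta` (decay, > 0), `noise_sd`
#'   (perturbation scale, > 0 for learning to occur), `lr_q` (learning
#'   step scale), `n_steps` (total simulation steps), and optionally
#'   `duration`, `dt`, `ctrl`, `seed`.  See `feedback_training_config()`.
#' @param normalize `TRUE`/`"global"` (default) rescales the trained
#'   `Q` by one global factor to mean unit column norm, preserving the
#'   learned relative channel gains; `"column"` rescales every column
#'   to unit norm, equalising the loop gain across error channels
#'   (useful when some output channels couple much more weakly than
#'   others); `FALSE` keeps raw magnitudes.
#' @return The network with its `Q` replaced by the trained matrix.
#' @export
train_feedback_weights <- function(net, inputs, cfg = feedback_training_config(),
                                   normalize = TRUE) {
  stopifnot(inherits(net, "dhdfc_network"))
  cfg <- utils::modifyList(feedback_training_config(), cfg)
  stopifnot(cfg$beta > 0, cfg$noise_sd >= 0, cfg$lr_q >= 0, cfg$n_steps >= 1)
  if (is.matrix(inputs)) inputs <- asplit(inputs, 1L)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  ls <- net$layer_sizes
  L <- length(ls)
  n_out <- ls[L]
  dt <- cfg$dt
  steps_per_trial <- as.integer(round(cfg$duration / dt))
  blocks <- q_row_blocks(net)
  Q <- net$Q
  total <- 0L
  i_input <- 0L

  while (total < cfg$n_steps) {
    i_input <- (i_input %% length(inputs)) + 1L
    x <- as.numeric(inputs[[i_input]])
    ff <- feedforward_pass(net, x)
    y_target <- ff$rates[[L]]          # noise-free output as its own target
    ctrl <- if (is.null(cfg$ctrl)) {
      # proportional-only by default: the integral path low-passes the
      # error, and its lag decorrelates c from the instantaneous
      # fluctuations the rule needs to pick up
      controller_state(n_out, k = 1, alpha = 1e6, tau_u = 1)
    } else cfg$ctrl
    v <- ff$potentials
    r <- ff$rates
    v_eq <- unlist(ff$potentials[2:L], use.names = FALSE)
    eps <- lapply(2:L, function(l) rep(0, ls[l]))
    hold <- max(1L, as.integer(cfg$noise_hold))
    for (s in seq_len(steps_per_trial)) {
      e <- y_target - r[[L]]
      st <- controller_step(ctrl, e, dt)
      ctrl <- st$state
      c_now <- st$c
      qc <- drop(Q %*% c_now)
      v_all <- unlist(v[2:L], use.names = FALSE) - v_eq
      Q <- Q + cfg$lr_q * dt * (-tcrossprod(v_all, c_now) - cfg$beta * Q)
      if (cfg$noise_sd > 0 && (s - 1L) %% hold == 0L) {
        eps <- lapply(2:L, function(l) stats::rnorm(ls[l], 0, cfg$noise_sd))
      }
      r_prev <- r
      for (l in 2:L) {
        drive <- drop(net$W[[l - 1L]] %*% r_prev[[l - 1L]]) + qc[blocks[[l - 1L]]] +
          eps[[l - 1L]]
        v[[l]] <- v[[l]] + dt * (-v[[l]] + drive)
        r[[l]] <- net$activation$f(v[[l]])
      }
      if (!all(is.finite(Q)) || !all(vapply(v[2:L], function(z) all(is.finite(z)), TRUE))) {
        stop("feedback-weight training became unstable; reduce lr_q or noise_sd",
             call. = FALSE)
      }
      total <- total + 1L
      if (total >= cfg$n_steps) break
    }
  }
  if (!isFALSE(normalize) && cfg$lr_q > 0) {
    if (identical(normalize, "column")) {
      nrm <- sqrt(colSums(Q^2))
      nrm[nrm == 0] <- 1
      Q <- sweep(Q, 2L, nrm, "/")
    } else {
      nrm <- norm(Q, "F")
      if (nrm > 0) Q <- Q * sqrt(ncol(Q)) / nrm
    }
  }
  net$Q <- Q
  validate_network(net)
  net
}

#' Default configuration for feedback-weight training
#'
#' @param beta Decay constant of the anti-Hebbian rule (> 0).
#' @param noise_sd Potential noise during pre-training.
#' @param lr_q Learning-step scale.
#' @param n_steps Total number of simulation steps.
#' @param duration,dt Trial horizon and Euler step.
#' @param noise_hold Number of steps each noise draw is held for
#'   (default 1: fresh white noise every step, as the learning rule is
#'   written; larger values give band-limited noise for
#'   experimentation).
#' @param seed Optional seed.
#' @param ctrl Optional `dhdfc_controller` to use during pre-training.
#' @return A named list.
#' @export
feedback_training_config <- function(beta = 0.1, noise_sd = 0.5, lr_q = 2,
                                     n_steps = 12000, duration = 3, dt = 0.01,
                                     noise_hold = 1, seed = NULL,
                                     ctrl = NULL) {
  list(beta = beta, noise_sd = noise_sd, lr_q = lr_q, n_steps = n_steps,
       duration = duration, dt = dt, noise_hold = noise_hold, seed = seed,
       ctrl = ctrl)
}

#' Save / load feedback weights
#'
#' `Q` matrices are stored as plain CSV with a JSON sidecar recording
#' the layer sizes they belong to.
#'
#' @param net A `dhdfc_network`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @export
save_feedback_weights <- function(net, path) {
  utils::write.table(net$Q, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(layer_sizes = net$layer_sizes,
                            activation = net$activation$name),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_feedback_weights
#' @export
load_feedback_weights <- function(net, path) {
  Q <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(Q) <- NULL
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!identical(as.integer(meta$layer_sizes), net$layer_sizes)) {
      stop("stored feedback weights were trained for layer sizes ",
           paste(meta$layer_sizes, collapse = "-"), call. = FALSE)
    }
  }
  net$Q <- Q
  validate_network(net)
  net
}
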