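#' Pairwise STDP kernel
#'
#' The classical spike-timing-dependent plasticity profile: a
#' pre-before-post spike pair at lag \eqn{\Delta t = t_{post} -
#' t_{pre} > 0} potentiates by \eqn{a_+ e^{-\Delta t/\tau_+}}, a
#' post-before-pre pair depresses by \eqn{a_- e^{-\Delta t/\tau_-}}.
#'
#' The default kernel is *balanced* (`a_plus * tau_plus == a_minus *
#' tau_minus`): the LTP and LTD lobes have equal area, so for constant
#' firing rates the expected pairwise update vanishes and what survives
#' is the temporal-derivative signal that the rate-based differential
#' Hebbian rule computes.  An unbalanced kernel adds a rate-product
#' offset to every synapse that can swamp that signal; see the methods
#' vignette.
#'
#' Time constants are expressed in the simulation time unit, the
#' membrane time constant.  Taking a cortical membrane constant of
#' ~100 ms, the default `tau_plus = tau_minus = 0.2` corresponds to the
#' classical ~20 ms STDP window.
#'
#' Pair sums are truncated at `window * max(tau_plus, tau_minus)`
#' (default 5 time constants, per-pair truncation error below
#' \eqn{e^{-5}}).
#'
#' @param a_plus,a_minus LTP / LTD amplitudes (>= 0).
#' @param tau_plus,tau_minus Kernel time constants in units of the
#'   membrane time constant (> 0).
#' @param pairing `"all_to_all"` (every pair within the window) or
#'   `"nearest_neighbor"` (each post spike pairs only with the most
#'   recent pre spike and vice versa).
#' @param window Truncation window in units of the larger time
#'   constant.
#' @return An object of class `dhdfc_stdp_kernel`.
#' @export
stdp_kernel <- function(a_plus = 0.01, a_minus = 0.01,
                        tau_plus = 0.2, tau_minus = 0.2,
                        pairing = c("all_to_all", "nearest_neighbor"),
                        window = 5) {
  pairing <- match.arg(pairing)
  stopifnot(a_plus >= 0, a_minus >= 0, tau_plus > 0, tau_minus > 0, window > 0)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, pairing = pairing, window = window),
            class = "dhdfc_stdp_kernel")
}

#' @export
print.dhdfc_stdp_kernel <- function(x, ...) {
  cat("<STDP kernel ", x$pairing, ": a+ = ", x$a_plus, ", a- = ", x$a_minus,
      ", tau+ = ", x$tau_plus, ", tau- = ", x$tau_minus, ">\n", sep = "")
  invisible(x)
}

# One Poisson realization as binary spike matrices (per layer, steps x
# neurons).  Rates are per-step spike probabilities.  Generation order
# (layer by layer, column-major within a layer) is fixed so that seeded
# runs are reproducible across every code path that consumes them.
poisson_spike_matrices <- function(traj, seed = NULL) {
  stopifnot(inherits(traj, "dhdfc_trajectory"))
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_along(traj$r), function(l) {
    R <- traj$r[[l]]
    bad <- which(R < 0 | R > 1)
    if (length(bad)) {
      ij <- arrayInd(bad[1L], dim(R))
      stop(sprintf(paste0("rate %.4f outside [0,1] at layer %d, neuron %d, ",
                          "step %d: rates are per-step spike probabilities"),
                   R[bad[1L]], l, ij[2L], ij[1L]), call. = FALSE)
    }
    matrix(stats::runif(length(R)) < R, nrow = nrow(R), ncol = ncol(R)) * 1
  })
}

#' Convert a rate trajectory to Poisson spike trains
#'
#' At every recorded step each neuron spikes independently with
#' probability equal to its instantaneous rate (an inhomogeneous
#' Bernoulli/Poisson process on the integration grid, so `dt` sets the
#' rate scale).  Identical seeds give identical trains.
#'
#' @param traj A `dhdfc_trajectory` whose rates all lie in \[0, 1\].
#' @param seed Optional integer seed.
#' @return An object of class `dhdfc_spiketrains`: `trains` is a list
#'   (per layer) of lists (per neuron) of strictly increasing spike
#'   times in \[0, duration\]; also carries `duration` and the source
#'   `dt`.
#' @export
rates_to_poisson_spikes <- function(traj, seed = NULL) {
  S <- poisson_spike_matrices(traj, seed)
  trains <- lapply(S, function(M) {
    lapply(seq_len(ncol(M)), function(j) traj$times[M[, j] > 0])
  })
  structure(list(trains = trains, duration = max(traj$times), dt = traj$dt,
                 layer_sizes = traj$layer_sizes),
            class = "dhdfc_spiketrains")
}

#' @export
print.dhdfc_spiketrains <- function(x, ...) {
  n <- sum(vapply(x$trains, function(l) sum(lengths(l)), 0))
  cat("<spike trains: ", n, " spikes over ", x$duration, " s>\n", sep = "")
  invisible(x)
}

#' Pairwise STDP update for one synapse
#'
#' Sums the exponential kernel over spike pairs of one presynaptic and
#' one postsynaptic train.  In `all_to_all` mode every pre-before-post
#' pair within the truncation window potentiates and every
#' post-before-pre pair depresses; `nearest_neighbor` restricts each
#' spike to its closest partner on the relevant side.  Simultaneous
#' spikes (\eqn{\Delta t = 0}) contribute nothing.
#'
#' @param pre,post Sorted numeric vectors of spike times (seconds).
#' @param kernel A `dhdfc_stdp_kernel`.
#' @return A single weight change.
#' @examples
#' k <- stdp_kernel(a_plus = 0.01, tau_plus = 0.02)
#' stdp_pairwise_update(0.010, 0.015, k)  # 0.01 * exp(-0.25)
#' @export
stdp_pairwise_update <- function(pre, post, kernel = stdp_kernel()) {
  stopifnot(inherits(kernel, "dhdfc_stdp_kernel"))
  pre <- as.numeric(pre); post <- as.numeric(post)
  if (is.unsorted(pre, strictly = FALSE) || is.unsorted(post, strictly = FALSE)) {
    stop("spike trains must be sorted in increasing time", call. = FALSE)
  }
  if (length(pre) == 0L || length(post) == 0L) return(0)
  wmax <- kernel$window * max(kernel$tau_plus, kernel$tau_minus)
  tol <- 1 + 1e-9
  if (kernel$pairing == "all_to_all") {
    dmat <- outer(post, pre, "-")      # t_post - t_pre
    ltp <- dmat[dmat > 0 & dmat <= wmax * tol]
    ltd <- -dmat[dmat < 0 & -dmat <= wmax * tol]
    sum(kernel$a_plus * exp(-ltp / kernel$tau_plus)) -
      sum(kernel$a_minus * exp(-ltd / kernel$tau_minus))
  } else {
    # each post spike with its most recent pre spike, each pre spike
    # with its most recent post spike
    dw <- 0
    idx <- findInterval(post - 1e-12, pre)
    ok <- idx >= 1L
    if (any(ok)) {
      d <- post[ok] - pre[idx[ok]]
      d <- d[d > 0 & d <= wmax * tol]
      dw <- dw + sum(kernel$a_plus * exp(-d / kernel$tau_plus))
    }
    idx <- findInterval(pre - 1e-12, post)
    ok <- idx >= 1L
    if (any(ok)) {
      d <- pre[ok] - post[idx[ok]]
      d <- d[d > 0 & d <= wmax * tol]
      dw <- dw - sum(kernel$a_minus * exp(-d / kernel$tau_minus))
    }
    dw
  }
}

# All-to-all pairwise STDP for a whole layer at once, computed on binary
# spike matrices via binned cross-correlation: identical to summing the
# exponential kernel over spike pairs on the dt grid, but vectorised as
# one small matrix product per lag.
stdp_layer_update <- function(S_pre, S_post, kernel, dt) {
  Tn <- nrow(S_pre)
  acc <- matrix(0, ncol(S_post), ncol(S_pre))
  wmax <- kernel$window * max(kernel$tau_plus, kernel$tau_minus)
  max_lag <- floor(wmax / dt * (1 + 1e-9))
  for (lag in seq_len(min(max_lag, Tn - 1L))) {
    lag_dt <- lag * dt
    if (lag_dt <= kernel$window * kernel$tau_plus * (1 + 1e-9)) {
      acc <- acc + (kernel$a_plus * exp(-lag_dt / kernel$tau_plus)) *
        crossprod(S_post[(1L + lag):Tn, , drop = FALSE],
                  S_pre[1:(Tn - lag), , drop = FALSE])
    }
    if (lag_dt <= kernel$window * kernel$tau_minus * (1 + 1e-9)) {
      acc <- acc - (kernel$a_minus * exp(-lag_dt / kernel$tau_minus)) *
        crossprod(S_post[1:(Tn - lag), , drop = FALSE],
                  S_pre[(1L + lag):Tn, , drop = FALSE])
    }
  }
  acc
}

#' Expected STDP update over Poisson realizations
#'
#' Converts the rate trajectory to spikes `n_realizations` times with
#' independent seeds, computes the all-to-all pairwise STDP update for
#' every synapse of the network on each realization, and returns the
#' mean.  Averaging over realizations suppresses the Poisson sampling
#' noise and exposes the rate-level expectation of STDP, which for the
#' balanced default kernel is proportional to the differential Hebbian
#' update.
#'
#' @param traj A `dhdfc_trajectory` whose rates all lie in \[0, 1\].
#' @param net The generating network (for synapse shapes).
#' @param kernel A `dhdfc_stdp_kernel` (`all_to_all` pairing).
#' @param n_realizations Number of independent Poisson conversions
#'   (>= 1).
#' @param seed Base seed; realization `i` uses `seed + i - 1`, so
#'   `n_realizations = 1` reproduces a single seeded conversion
#'   exactly.
#' @return A `dhdfc_updates` with rule `"STDP"`.
#' @export
stdp_expected_update <- function(traj, net, kernel = stdp_kernel(),
                                 n_realizations = 1, seed = NULL) {
  stopifnot(inherits(traj, "dhdfc_trajectory"), n_realizations >= 1)
  if (kernel$pairing != "all_to_all") {
    stop("expected updates are implemented for all_to_all pairing",
         call. = FALSE)
  }
  L <- length(traj$layer_sizes)
  acc <- lapply(2:L, function(l) {
    matrix(0, traj$layer_sizes[l], traj$layer_sizes[l - 1L])
  })
  for (i in seq_len(n_realizations)) {
    s_i <- if (is.null(seed)) NULL else seed + i - 1L
    S <- poisson_spike_matrices(traj, s_i)
    for (l in 2:L) {
      acc[[l - 1L]] <- acc[[l - 1L]] +
        stdp_layer_update(S[[l - 1L]], S[[l]], kernel, traj$dt)
    }
  }
  update_set(lapply(acc, function(m) m / n_realizations), "STDP")
}
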