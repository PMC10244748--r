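#' Construct an update set
#'
#' A per-layer collection of weight-update matrices produced by one
#' plasticity rule, with shapes matching the network's feedforward
#' weights so that updates from different rules can be compared
#' synapse by synapse.
#'
#' @param deltas List of matrices, one per weight matrix `W[[l]]`.
#' @param rule One of `"DH"`, `"delta"`, `"BP"`, `"STDP"`.
#' @return An object of class `dhdfc_updates`.
#' @export
update_set <- function(deltas, rule = c("DH", "delta", "BP", "STDP")) {
  rule <- match.arg(rule)
  stopifnot(is.list(deltas))
  if (!all(vapply(deltas, function(d) all(is.finite(d)), TRUE))) {
    stop("non-finite entries in weight update", call. = FALSE)
  }
  structure(list(deltas = deltas, rule = rule), class = "dhdfc_updates")
}

#' @export
print.dhdfc_updates <- function(x, ...) {
  cat("<", x$rule, " update set, ", length(x$deltas), " layers, max |dw| = ",
      signif(max(abs(unlist(x$deltas))), 3), ">\n", sep = "")
  invisible(x)
}

#' Flatten an update set to a single numeric vector
#' @param us A `dhdfc_updates`.
#' @export
flatten_updates <- function(us) {
  stopifnot(inherits(us, "dhdfc_updates"))
  unlist(lapply(us$deltas, as.numeric), use.names = FALSE)
}

#' Elementwise arithmetic on update sets
#' @param e1,e2 `dhdfc_updates` objects (or a scalar for `*`).
#' @export
Ops.dhdfc_updates <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*")) {
    stop("operation ", .Generic, " not defined for update sets", call. = FALSE)
  }
  if (.Generic == "*" && is.numeric(e2)) {
    return(update_set(lapply(e1$deltas, function(d) d * e2), e1$rule))
  }
  if (.Generic == "*" && is.numeric(e1)) {
    return(update_set(lapply(e2$deltas, function(d) d * e1), e2$rule))
  }
  stopifnot(inherits(e1, "dhdfc_updates"), inherits(e2, "dhdfc_updates"))
  update_set(Map(function(a, b) get(.Generic)(a, b), e1$deltas, e2$deltas),
             e1$rule)
}

check_traj_for_update <- function(traj) {
  stopifnot(inherits(traj, "dhdfc_trajectory"))
  if (length(traj$times) < 2L) {
    stop("plasticity rules need a trajectory with at least 2 steps",
         call. = FALSE)
  }
}

#' Differential Hebbian weight update from a trajectory
#'
#' For every synapse the update integrates presynaptic rate times the
#' temporal derivative of the postsynaptic rate,
#' \deqn{\Delta w = \sum_t r_{pre}(t)\,[r_{post}(t+dt) - r_{post}(t)],}
#' using forward differences with the presynaptic rate taken at the
#' earlier step (pre-before-post causality, matching the LTP sign
#' convention of pairwise STDP).  The proportionality constant is 1;
#' the learning rate is applied by the caller.  Input-layer rates serve
#' as `r_pre` for the first hidden layer.
#'
#' @param traj A `dhdfc_trajectory` with at least 2 recorded steps.
#' @param net The network the trajectory was generated from (for
#'   shapes).
#' @param online If `TRUE`, accumulate the update step by step in a
#'   loop instead of as one matrix product; the result is identical and
#'   this path exists to mirror an online biological implementation.
#' @return A `dhdfc_updates` with rule `"DH"`.
#' @export
dh_update <- function(traj, net, online = FALSE) {
  check_traj_for_update(traj)
  L <- length(traj$layer_sizes)
  deltas <- vector("list", L - 1L)
  Tn <- length(traj$times)
  for (l in 2:L) {
    pre <- traj$r[[l - 1L]]
    post <- traj$r[[l]]
    if (online) {
      acc <- matrix(0, ncol(post), ncol(pre))
      for (s in seq_len(Tn - 1L)) {
        acc <- acc + tcrossprod(post[s + 1L, ] - post[s, ], pre[s, ])
      }
      deltas[[l - 1L]] <- acc
    } else {
      dpost <- post[-1L, , drop = FALSE] - post[-Tn, , drop = FALSE]
      deltas[[l - 1L]] <- crossprod(dpost, pre[-Tn, , drop = FALSE])
    }
  }
  update_set(deltas, "DH")
}

#' Dendritic-error (delta) weight update from a trajectory
#'
#' \deqn{\Delta w = r_{pre}(T)\,[r_{post}(T) - r_{post}(0)],}
#' the update used by dendritic-error learning: presynaptic rate times
#' the total feedback-induced change of the postsynaptic rate.  When
#' the presynaptic rate is constant over the trajectory this equals the
#' differential Hebbian update exactly (telescoping sum).
#'
#' @inheritParams dh_update
#' @return A `dhdfc_updates` with rule `"delta"`.
#' @export
delta_update <- function(traj, net) {
  check_traj_for_update(traj)
  L <- length(traj$layer_sizes)
  Tn <- length(traj$times)
  deltas <- vector("list", L - 1L)
  for (l in 2:L) {
    pre_T <- traj$r[[l - 1L]][Tn, ]
    dpost <- traj$r[[l]][Tn, ] - traj$r[[l]][1L, ]
    deltas[[l - 1L]] <- tcrossprod(dpost, pre_T)
  }
  update_set(deltas, "delta")
}

#' Backpropagation reference update
#'
#' Exact gradient of the squared output error
#' \eqn{\tfrac12\lVert y^* - r_{out}\rVert^2} of the open-loop
#' feedforward pass with respect to each weight matrix, negated so that
#' it is a descent direction directly comparable with the Hebbian
#' updates.  This is the machine-learning baseline the biologically
#' plausible rules are measured against.
#'
#' @param net A `dhdfc_network`.
#' @param x Input vector.
#' @param y_target Target output rates.
#' @return A `dhdfc_updates` with rule `"BP"`.
#' @export
bp_update <- function(net, x, y_target) {
  stopifnot(inherits(net, "dhdfc_network"))
  ff <- feedforward_pass(net, x)
  L <- length(net$layer_sizes)
  y_target <- as.numeric(y_target)
  if (length(y_target) != net$layer_sizes[L]) {
    stop("y_target length does not match the output layer", call. = FALSE)
  }
  deltas <- vector("list", L - 1L)
  err <- (y_target - ff$rates[[L]]) * net$activation$grad(ff$potentials[[L]])
  for (l in (L - 1L):1L) {
    deltas[[l]] <- tcrossprod(err, ff$rates[[l]])
    if (l > 1L) {
      err <- drop(crossprod(net$W[[l]], err)) *
        net$activation$grad(ff$potentials[[l]])
    }
  }
  update_set(deltas, "BP")
}

#' Coefficient of determination between two update sets
#'
#' Flattens both update sets over all synapses and returns the
#' \eqn{R^2} of the least-squares fit of the entries of `b` against the
#' entries of `a` (with intercept) — the statistic used to quantify how
#' well two plasticity rules agree.
#'
#' @param a,b `dhdfc_updates` with matching shapes.
#' @return A single number in \[0, 1\].
#' @export
update_correlation <- function(a, b) {
  va <- flatten_updates(a)
  vb <- flatten_updates(b)
  if (length(va) != length(vb)) {
    stop("update sets have different total sizes", call. = FALSE)
  }
  if (stats::var(va) == 0 || stats::var(vb) == 0) {
    stop("zero-variance update set: correlation is undefined", call. = FALSE)
  }
  stats::cor(va, vb)^2
}

#' Least-squares slope between two update sets
#'
#' Slope of the regression of `b`'s entries on `a`'s entries (with
#' intercept); used alongside [update_correlation()] to check the sign
#' of the alignment between rules.
#'
#' @inheritParams update_correlation
#' @export
update_slope <- function(a, b) {
  va <- flatten_updates(a)
  vb <- flatten_updates(b)
  if (stats::var(va) == 0) {
    stop("zero-variance update set: slope is undefined", call. = FALSE)
  }
  stats::cov(va, vb) / stats::var(va)
}

#' Export an update set as a flat CSV
#'
#' One row per synapse with layer, row (postsynaptic) and column
#' (presynaptic) indices — the format used for cross-rule scatter
#' plots.
#'
#' @param us A `dhdfc_updates`.
#' @param path Output CSV path.
#' @export
write_update_csv <- function(us, path) {
  rows <- do.call(rbind, lapply(seq_along(us$deltas), function(l) {
    d <- us$deltas[[l]]
    data.frame(layer = l,
               post = as.vector(row(d)),
               pre = as.vector(col(d)),
               dw = as.vector(d))
  }))
  rows$rule <- us$rule
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Apply an update set to a network
#'
#' @param net A `dhdfc_network`.
#' @param us A `dhdfc_updates`.
#' @param lr Learning rate multiplier: a scalar, or one value per
#'   weight matrix.
#' @return The network with `W[[l]] + lr[l] * deltas[[l]]`.
#' @export
apply_updates <- function(net, us, lr = 1) {
  stopifnot(inherits(net, "dhdfc_network"), inherits(us, "dhdfc_updates"))
  lr <- rep_len(lr, length(net$W))
  for (l in seq_along(net$W)) {
    net$W[[l]] <- net$W[[l]] + lr[l] * us$deltas[[l]]
  }
  validate_network(net)
  net
}
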