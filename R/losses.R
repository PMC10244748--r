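#' Initial mean squared error of a trajectory
#'
#' The distance between the target and the *initial* output activity,
#' before the feedback controller has acted: closed-loop trajectories
#' start at the open-loop equilibrium, so this is the loss a standard
#' machine-learning pipeline would report for the feedforward network.
#'
#' @param traj A `dhdfc_trajectory`.
#' @param y_target Target output rates.
#' @return Mean over output neurons of the squared initial error.
#' @export
mse_loss <- function(traj, y_target) {
  stopifnot(inherits(traj, "dhdfc_trajectory"))
  r0 <- output_rates(traj)[1L, ]
  y_target <- as.numeric(y_target)
  if (length(y_target) != length(r0)) {
    stop("y_target length does not match the output layer", call. = FALSE)
  }
  mean((y_target - r0)^2)
}

#' Feedback cost of a trajectory
#'
#' The amount of top-down feedback spent during the presentation,
#' \deqn{H = \sum_t \lVert c(t)\rVert^2\, dt,}
#' the squared-norm integral of the controller signal (the control-cost
#' convention of feedback-based training frameworks).  `squared =
#' FALSE` gives the plain-norm integral instead.
#'
#' @param traj A `dhdfc_trajectory` with a recorded controller signal.
#' @param squared Integrate the squared norm (default) or the plain
#'   norm.
#' @return A single non-negative number (control^2 x seconds).
#' @export
feedback_cost <- function(traj, squared = TRUE) {
  stopifnot(inherits(traj, "dhdfc_trajectory"))
  if (is.null(traj$c)) stop("trajectory has no controller record", call. = FALSE)
  nrm2 <- rowSums(traj$c^2)
  if (squared) sum(nrm2) * traj$dt else sum(sqrt(nrm2)) * traj$dt
}

#' Time to reach the output target
#'
#' The first time at which the output error falls below `tol` (in the
#' max norm) *and stays below it for the remainder of the trial* —
#' requiring sustained convergence avoids counting transient crossings.
#' Returns `Inf` when the target is never reached within the trial.
#'
#' @param traj A closed-loop `dhdfc_trajectory` (with `e` recorded).
#' @param tol Error tolerance in rate units (> 0); default 0.1.
#' @return Time in seconds, or `Inf`.
#' @export
time_to_target <- function(traj, tol = 0.1) {
  stopifnot(inherits(traj, "dhdfc_trajectory"), tol > 0)
  if (is.null(traj$e)) stop("trajectory has no error record", call. = FALSE)
  below <- apply(abs(traj$e), 1L, max) < tol
  # last index from which `below` holds through the end
  ok <- rev(cumprod(rev(below)))
  idx <- which(ok > 0)
  if (length(idx) == 0L) return(Inf)
  traj$times[idx[1L]]
}
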