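#' Two-input single-neuron task
#'
#' The elementary supervision task: one output neuron receives input
#' from two presynaptic neurons A and B with fixed rates, and the
#' teaching feedback asks for a low output rate when A dominates and a
#' high rate when B dominates.  Stimuli alternate A, B, A, B, ...
#'
#' @param n_pairs Number of A/B presentation pairs.
#' @param rate_hi,rate_lo Firing rate of the dominant / background
#'   input neuron (defaults 0.8 / 0.2, so both synapses are active in
#'   every trial).
#' @param target_hi,target_lo Target output rates for B- and A-trials;
#'   defaults 0.95 / 0.05, the one-hot levels reachable by a sigmoid.
#' @param seed Optional seed (the sequence is deterministic; the seed
#'   is accepted for interface uniformity and reproducible downstream
#'   use).
#' @return Data frame with columns `stim` ("A"/"B"), `r_A`, `r_B`,
#'   `target`.
#' @export
gen_two_input_task <- function(n_pairs = 1, rate_hi = 0.8, rate_lo = 0.2,
                               target_hi = 0.95, target_lo = 0.05,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    stim = rep(c("A", "B"), n_pairs),
    r_A = rep(c(rate_hi, rate_lo), n_pairs),
    r_B = rep(c(rate_lo, rate_hi), n_pairs),
    target = rep(c(target_lo, target_hi), n_pairs)
  )
}

#' Multi-class Gaussian-blob classification task
#'
#' Synthetic stand-in for an image benchmark: `n_classes` isotropic
#' unit-variance Gaussian clouds whose centers are placed on a randomly
#' rotated circle so that every pair of adjacent centers is exactly
#' `sep` standard deviations apart (non-adjacent pairs are farther).
#' With `sep` well above ~4 the Bayes error is negligible and any
#' failure to classify is attributable to the learning rule, not the
#' task.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Samples per class (0 gives an empty set).
#' @param dim Input dimensionality (>= 2; the center circle is embedded
#'   in a random 2-D subspace).
#' @param sep Minimum pairwise center distance in units of the
#'   within-class standard deviation (> 0).
#' @param seed Optional seed; identical seeds give identical datasets.
#' @param target_hi,target_lo One-hot target levels mapped into the
#'   sigmoid range (defaults 0.95 / 0.05).
#' @return List with `x` (n x dim matrix), `labels` (integer classes
#'   1..K), `targets` (n x K matrix of one-hot rates), `centers`.
#' @export
gen_gaussian_classification <- function(n_classes, n_per_class, dim = 2,
                                        sep = 6, seed = NULL,
                                        target_hi = 0.95, target_lo = 0.05) {
  stopifnot(n_classes >= 2, n_per_class >= 0, dim >= 2, sep > 0)
  if (!is.null(seed)) set.seed(seed)
  radius <- sep / (2 * sin(pi / n_classes))
  theta0 <- stats::runif(1, 0, 2 * pi)
  angles <- theta0 + 2 * pi * (seq_len(n_classes) - 1) / n_classes
  circle <- cbind(radius * cos(angles), radius * sin(angles))
  # embed the circle in a random 2-D subspace of R^dim
  basis <- qr.Q(qr(matrix(stats::rnorm(dim * 2), dim, 2)))
  centers <- circle %*% t(basis)

  n <- n_classes * n_per_class
  labels <- rep(seq_len(n_classes), each = n_per_class)
  x <- matrix(stats::rnorm(n * dim), n, dim) + centers[labels, , drop = FALSE]
  targets <- matrix(target_lo, n, n_classes)
  if (n > 0) targets[cbind(seq_len(n), labels)] <- target_hi
  list(x = x, labels = labels, targets = targets, centers = centers)
}

#' Map raw features to clamped input rates
#'
#' Network inputs are clamped firing rates, so real-valued features are
#' standardised per column and squashed through the sigmoid into
#' (0, 1).  This keeps inputs compatible with both the rate dynamics
#' and the Poisson spike conversion (which reads rates as per-step
#' spike probabilities).
#'
#' @param x Numeric matrix (rows = samples).
#' @param center,scale Optional precomputed column means / standard
#'   deviations (e.g., from a training set).
#' @return Matrix of the same shape with entries in (0, 1); the
#'   standardisation used is attached as attributes `center` and
#'   `scale`.
#' @export
prepare_rate_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  out <- 1 / (1 + exp(-z))
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Nearest-centroid oracle classifier
#'
#' A deliberately simple reference classifier (fit class centroids,
#' predict the closest) used to confirm that the synthetic tasks are
#' essentially linearly separable before a learning rule is blamed for
#' failing on them.
#'
#' @param dataset A dataset from [gen_gaussian_classification()].
#' @return Training accuracy of the centroid classifier.
#' @export
centroid_oracle_accuracy <- function(dataset) {
  centers <- do.call(rbind, lapply(sort(unique(dataset$labels)), function(k) {
    colMeans(dataset$x[dataset$labels == k, , drop = FALSE])
  }))
  d2 <- outer(rowSums(dataset$x^2), rowSums(centers^2), "+") -
    2 * dataset$x %*% t(centers)
  mean(max.col(-d2) == dataset$labels)
}
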