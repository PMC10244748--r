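#' Activation functions for rate neurons
#'
#' Constructs an activation function object holding the forward map
#' \eqn{\phi} and its derivative \eqn{\phi'}.  The sigmoid is the default
#' neuronal nonlinearity: it maps membrane potential to a firing
#' probability in (0, 1), which is also what the Poisson spike conversion
#' expects.  `tanh` and `linear` are provided for diagnostics and tests.
#'
#' @param name One of `"sigmoid"`, `"tanh"`, `"linear"`.
#' @return An object of class `dhdfc_activation` with elements `name`,
#'   `f` (the map), `grad` (its derivative) and `inv` (its inverse on
#'   the open range).
#' @examples
#' act <- activation_fn("sigmoid")
#' act$f(0)        # 0.5
#' act$grad(0)     # 0.25
#' @export
activation_fn <- function(name = c("sigmoid", "tanh", "linear")) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("sigmoid", "tanh", "linear")) {
    stop("unknown activation name: ", paste(name, collapse = ", "),
         " (expected one of 'sigmoid', 'tanh', 'linear')", call. = FALSE)
  }
  fns <- switch(name,
    sigmoid = list(
      f    = function(v) 1 / (1 + exp(-v)),
      grad = function(v) {
        s <- 1 / (1 + exp(-v))
        s * (1 - s)
      },
      inv  = function(r) log(r / (1 - r))
    ),
    tanh = list(
      f    = function(v) tanh(v),
      grad = function(v) 1 - tanh(v)^2,
      inv  = function(r) atanh(r)
    ),
    linear = list(
      f    = function(v) v,
      grad = function(v) rep(1, length(v)),
      inv  = function(r) r
    )
  )
  structure(list(name = name, f = fns$f, grad = fns$grad, inv = fns$inv),
            class = "dhdfc_activation")
}

#' Apply an activation function elementwise
#'
#' @param act A `dhdfc_activation` (or the name of one).
#' @param v Numeric vector of membrane potentials; must be finite.
#' @param derivative If `TRUE`, apply \eqn{\phi'} instead of \eqn{\phi}.
#' @return Numeric vector of the same length as `v`.
#' @export
activation_apply <- function(act, v, derivative = FALSE) {
  if (is.character(act)) act <- activation_fn(act)
  stopifnot(inherits(act, "dhdfc_activation"))
  if (!all(is.finite(v))) {
    stop("non-finite membrane potential passed to activation", call. = FALSE)
  }
  if (isTRUE(derivative)) act$grad(v) else act$f(v)
}

#' @export
print.dhdfc_activation <- function(x, ...) {
  cat("<activation:", x$name, ">\n")
  invisible(x)
}
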