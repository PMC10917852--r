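#' Construct a jet
#'
#' A k-jet is a curve's position and first k derivatives at one parameter
#' value: the tuple `(x0, x1, ..., xk)` attached to a timestamp `t`. Jets
#' are the objects the group of diffeomorphisms acts on when mapping
#' traces with derivative information.
#'
#' @param t scalar timestamp (arc-length parameter, microns).
#' @param x list of `k + 1` 3-vectors: position, then derivatives.
#' @return an object of class `jet` with fields `t`, `x`, `order`.
#' @seealso [jet_transform()], [prolong()]
#' @export
jet <- function(t, x) {
  if (!is.list(x)) x <- list(x)
  x <- lapply(x, as.numeric)
  stopifnot(length(x) >= 1L, all(lengths(x) == 3L))
  k <- length(x) - 1L
  if (k > 2L) stop("jets of order > 2 are not supported")
  structure(list(t = as.numeric(t), x = x, order = k), class = "jet")
}

#' Apply a diffeomorphism to a jet
#'
#' The jet-space group action: the position goes through the map, the
#' first derivative through the Jacobian, and the second derivative picks
#' up the Hessian's bending of the first derivative,
#'
#' \deqn{(t, x_0, x_1, x_2) \mapsto
#'   (t, \phi(x_0),\; D\phi(x_0)\,x_1,\;
#'    D\phi(x_0)\,x_2 + D^2\phi(x_0)(x_1, x_1)).}
#'
#' The timestamp is unchanged. This action commutes with composing the
#' map with the underlying curve, which is what makes transported
#' derivatives meaningful.
#'
#' @param phi a `diffeo`; must provide derivatives up to the jet's order
#'   (Jacobian analytically or by finite differences; Hessian analytic
#'   only).
#' @param x a `jet`, or a list of jets (a jet sequence), transformed
#'   elementwise.
#' @return the transformed jet(s).
#' @export
jet_transform <- function(phi, x) {
  if (is.list(x) && !inherits(x, "jet"))
    return(lapply(x, function(j) jet_transform(phi, j)))
  stopifnot(inherits(x, "jet"))
  x0 <- x$x[[1L]]
  out <- list(phi_apply(phi, x0))
  if (x$order >= 1L) {
    J <- phi_jacobian(phi, x0)
    out[[2L]] <- drop(J %*% x$x[[2L]])
    if (x$order == 2L) {
      H <- phi_hessian(phi, x0)
      x1 <- x$x[[2L]]
      quad <- vapply(1:3, function(a) drop(t(x1) %*% H[a, , ] %*% x1), 0)
      out[[3L]] <- drop(J %*% x$x[[3L]]) + quad
    }
  }
  jet(x$t, out)
}

#' Prolong a branch to a sequence of jets
#'
#' Lifts the piecewise-linear branch into jet space. For `k = 0` each
#' knot becomes a position-only jet. For `k = 1` the lift is per segment:
#' on `[x_i, x_{i+1}]` both endpoint derivatives equal the unit chord
#' `(x_{i+1} - x_i) / |x_{i+1} - x_i|`, i.e. one-sided derivatives of the
#' first-order spline, so an interior knot carries a (possibly different)
#' derivative on each side. Because branches are arc-length
#' parameterized the chords have unit norm; mapped derivatives are used
#' as-is, without renormalization.
#'
#' @param branch a `branch` (from [decompose_branches()]) with at least 2
#'   knots.
#' @param k jet order, 0 or 1.
#' @return for `k = 0`, a list of per-knot `jet`s; for `k = 1`, a list
#'   with one element per segment, each a list of the two endpoint jets
#'   `(j0, j1)`.
#' @export
prolong <- function(branch, k = 1L) {
  stopifnot(inherits(branch, "branch"), k %in% c(0L, 1L))
  m <- nrow(branch$knots)
  if (m < 2L) stop("branch must have at least 2 knots")
  if (k == 0L)
    return(lapply(seq_len(m), function(i)
      jet(branch$timestamps[i], list(branch$knots[i, ]))))
  lapply(seq_len(m - 1L), function(i) {
    d <- branch$knots[i + 1L, ] - branch$knots[i, ]
    L <- .eucl(d)
    if (L <= 0) stop("degeneracy error: zero-length segment at knot ", i)
    u <- d / L
    list(j0 = jet(branch$timestamps[i], list(branch$knots[i, ], u)),
         j1 = jet(branch$timestamps[i + 1L], list(branch$knots[i + 1L, ], u)))
  })
}
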