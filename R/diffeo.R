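#' Construct a diffeomorphism
#'
#' Wraps a position map of 3-space (microns to microns) together with
#' optional analytic derivatives. When the Jacobian is absent it is
#' supplied on demand by forward finite differences
#' ([finite_diff_jacobian()]) with step `fd_step`; the Hessian, needed
#' only for the order-2 jet action, has no finite-difference fallback and
#' its absence is a capability error at the point of use.
#'
#' @param map function taking a 3-vector (or n x 3 matrix) and returning
#'   its image, same shape.
#' @param jacobian optional function: 3-vector -> 3 x 3 matrix `J[a, b] =
#'   d map_a / d x_b`.
#' @param hessian optional function: 3-vector -> 3 x 3 x 3 array
#'   `H[a, b, c] = d^2 map_a / (d x_b d x_c)`, symmetric in `b, c`.
#' @param domain optional list(lower, upper): axis-aligned box outside
#'   which evaluation errors (used by generated deformations).
#' @param descriptor free-form provenance record.
#' @param fd_step forward-difference step in microns used when `jacobian`
#'   is absent (1e-5 suits analytic maps; generated displacement fields
#'   use 1e-3).
#' @param vectorized set `TRUE` if `map` accepts an n x 3 matrix of row
#'   points; otherwise it is applied row by row.
#' @return an object of class `diffeo`.
#' @seealso [affine_diffeo()], [random_diffeomorphism()], [jet_transform()]
#' @export
diffeomorphism <- function(map, jacobian = NULL, hessian = NULL,
                           domain = NULL, descriptor = "analytic",
                           fd_step = 1e-5, vectorized = FALSE) {
  stopifnot(is.function(map))
  structure(list(map = map, jacobian = jacobian, hessian = hessian,
                 domain = domain, descriptor = descriptor,
                 fd_step = fd_step, vectorized = isTRUE(vectorized)),
            class = "diffeo")
}

#' Affine transformation as a diffeomorphism
#'
#' `x -> A x + b`, with exact Jacobian `A` and zero Hessian. Affine maps
#' carry straight segments to straight segments, so both zeroth- and
#' first-order mapping reproduce the dense ground truth exactly under
#' them; they are the natural exactness fixture.
#'
#' @param A 3 x 3 matrix with positive determinant.
#' @param b length-3 translation.
#' @return a `diffeo`.
#' @export
affine_diffeo <- function(A, b = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3L, 3L)
  b <- as.numeric(b)
  if (det(A) <= 0) stop("affine map must have positive determinant")
  diffeomorphism(
    map = function(x) {
      if (is.matrix(x)) sweep(x %*% t(A), 2L, b, "+") else drop(A %*% x) + b
    },
    jacobian = function(x) A,
    hessian = function(x) array(0, c(3L, 3L, 3L)),
    descriptor = "affine", vectorized = TRUE)
}

#' Evaluate a diffeomorphism
#'
#' Applies the position map to one point (length-3 vector) or many
#' (n x 3 matrix of row points), enforcing the transformation's domain:
#' querying outside the grid of a generated deformation is an error, not
#' an extrapolation.
#'
#' @param phi a `diffeo`.
#' @param x 3-vector or n x 3 matrix, microns.
#' @return image point(s), same shape as `x`.
#' @export
phi_apply <- function(phi, x) {
  single <- !is.matrix(x)
  m <- if (single) matrix(as.numeric(x), 1L) else x
  if (!is.null(phi$domain)) {
    lo <- phi$domain$lower; hi <- phi$domain$upper
    out <- m[, 1L] < lo[1L] | m[, 1L] > hi[1L] |
           m[, 2L] < lo[2L] | m[, 2L] > hi[2L] |
           m[, 3L] < lo[3L] | m[, 3L] > hi[3L]
    if (any(out))
      stop("domain error: point (",
           paste(signif(m[which(out)[1L], ], 6L), collapse = ", "),
           ") lies outside the transformation's grid")
  }
  y <- if (phi$vectorized) phi$map(m)
       else t(apply(m, 1L, function(p) as.numeric(phi$map(p))))
  if (single) as.numeric(y) else y
}

#' Forward-difference Jacobian of a transformation
#'
#' Approximates `D phi(x)` column by column as
#' `(phi(x + h e_j) - phi(x)) / h`, costing four map evaluations. Exact
#' for affine maps; first-order accurate (error `O(h)`) otherwise.
#'
#' @param phi a `diffeo` (its analytic Jacobian, if any, is ignored here).
#' @param x 3-vector evaluation point.
#' @param h step in microns.
#' @return a 3 x 3 Jacobian matrix.
#' @export
finite_diff_jacobian <- function(phi, x, h = phi$fd_step) {
  stopifnot(h > 0)
  x <- as.numeric(x)
  pts <- rbind(x, x + c(h, 0, 0), x + c(0, h, 0), x + c(0, 0, h))
  y <- unname(phi_apply(phi, pts))
  t(y[-1L, , drop = FALSE] - rep(1, 3L) %o% y[1L, ]) / h
}

#' Jacobian of a diffeomorphism at a point
#'
#' Analytic when available, otherwise forward finite differences with the
#' transformation's default step.
#'
#' @inheritParams finite_diff_jacobian
#' @return a 3 x 3 matrix.
#' @export
phi_jacobian <- function(phi, x, h = phi$fd_step) {
  if (!is.null(phi$jacobian)) phi$jacobian(as.numeric(x))
  else finite_diff_jacobian(phi, x, h)
}

phi_hessian <- function(phi, x) {
  if (is.null(phi$hessian))
    stop("capability error: transformation provides no Hessian, ",
         "required for the order-2 jet action")
  phi$hessian(as.numeric(x))
}

#' Compose two diffeomorphisms
#'
#' Returns `f o g` (apply `g` first). Derivatives are chained exactly when
#' both factors supply them: `D(f o g) = Df(g) Dg`, and the Hessian picks
#' up both the transported Hessian of `f` and the bent Jacobian term
#' `Df(g) D2g`. Used to exercise the compatibility axiom of the jet-space
#' group action.
#'
#' @param f,g `diffeo` objects.
#' @return a `diffeo` computing `f(g(x))`.
#' @export
compose_diffeo <- function(f, g) {
  jac <- if (!is.null(f$jacobian) && !is.null(g$jacobian)) {
    function(x) f$jacobian(g$map(x)) %*% g$jacobian(x)
  }
  hes <- if (!is.null(f$hessian) && !is.null(g$hessian) &&
             !is.null(f$jacobian) && !is.null(g$jacobian)) {
    function(x) {
      gx <- g$map(x); Jg <- g$jacobian(x)
      Hf <- f$hessian(gx); Jf <- f$jacobian(gx); Hg <- g$hessian(x)
      H <- array(0, c(3L, 3L, 3L))
      for (a in 1:3) {
        # t(Jg) %*% Hf[a,,] %*% Jg transports f's curvature through g
        H[a, , ] <- t(Jg) %*% Hf[a, , ] %*% Jg
        for (p in 1:3) H[a, , ] <- H[a, , ] + Jf[a, p] * Hg[p, , ]
      }
      H
    }
  }
  diffeomorphism(map = function(x) phi_apply(f, phi_apply(g, x)),
                 jacobian = jac, hessian = hes,
                 descriptor = "composition", vectorized = TRUE)
}

#' Displacement profile of a transformation on a regular grid
#'
#' Summarizes how far a transformation moves positions and bends unit
#' tangents: at each grid point `x` the position displacement is
#' `|phi(x) - x|` and the tangent displacements are `|Dphi(x) v - v|` for
#' `v` each of the three axis directions. These profiles let users place
#' a transformation of interest on the severity scale spanned by the
#' random-deformation generator's noise levels.
#'
#' @param phi a `diffeo`.
#' @param grid_spacing grid pitch in microns (500 matches the scale at
#'   which such profiles are usually histogrammed).
#' @param extent half-width of the sampling box per axis, microns; by
#'   default the transformation's own domain is used.
#' @return list with numeric vectors `position` and `tangent`.
#' @export
displacement_profile <- function(phi, grid_spacing = 500, extent = NULL) {
  if (is.null(extent)) {
    if (is.null(phi$domain))
      stop("extent must be given for transformations without a stored domain")
    lo <- phi$domain$lower; hi <- phi$domain$upper
  } else {
    extent <- rep_len(as.numeric(extent), 3L)
    lo <- -extent; hi <- extent
  }
  if (!is.null(phi$domain) && is.null(phi$jacobian)) {
    # leave room for the forward-difference stencil at the upper faces
    hi <- hi - 2 * phi$fd_step
  }
  ax <- lapply(1:3, function(i) seq(lo[i], hi[i], by = grid_spacing))
  g <- as.matrix(expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]]))
  pos_disp <- .row_norms(phi_apply(phi, g) - g)
  tan_disp <- unlist(lapply(seq_len(nrow(g)), function(i) {
    J <- phi_jacobian(phi, g[i, ])
    vapply(1:3, function(j) .eucl(J[, j] - diag(3L)[, j]), 0)
  }))
  list(position = pos_disp, tangent = tan_disp)
}
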