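#' Worst-case zeroth-order mapping error from the Jacobian
#'
#' Computes the Jacobian-based upper bound on the error of zeroth-order
#' mapping of an arc-length-parameterized piecewise-linear curve `c`
#' under a C1 diffeomorphism `phi`: writing `f = phi o c` for the
#' transformed curve and `g` for its first-order (position-only) spline,
#'
#' \deqn{\max_t |f(t) - g(t)| \le \max_{i,\; t \in [t_{i-1}, t_i]}
#'   \tfrac12 \big( \|D\phi(c(t)) - I\|_2 \, |t_i - t_{i-1}|
#'   + |\epsilon_i - \epsilon_{i-1}| \big),}
#'
#' where `eps_i = c(t_i) - phi(c(t_i))` is the knot displacement and the
#' matrix norm is spectral. The bound vanishes as `phi` approaches the
#' identity (and under pure translations) and grows with segment length
#' and with how far the Jacobian strays from the identity.
#'
#' The supremum over `t` within each interval is approximated by probing
#' `n_probe` equispaced parameter values, so the reported number is a
#' dense lower estimate of the exact supremum; the per-interval probe
#' maxima are returned for inspection.
#'
#' @param branch a `branch` (arc-length timestamps guaranteed by type).
#' @param phi a `diffeo` with Jacobian access.
#' @param n_probe probe points per knot interval (>= 2).
#' @return a `bound_report`: `bound_value` (microns), `per_interval_terms`,
#'   `knot_spacing_delta` (max interval length), `n_probe`.
#' @export
jacobian_error_bound <- function(branch, phi, n_probe = 100) {
  stopifnot(inherits(branch, "branch"))
  if (n_probe < 2) stop("parameter error: n_probe must be >= 2")
  m <- nrow(branch$knots)
  knot_img <- phi_apply(phi, branch$knots)
  eps <- branch$knots - knot_img
  terms <- numeric(m - 1L)
  for (i in seq_len(m - 1L)) {
    dt <- branch$timestamps[i + 1L] - branch$timestamps[i]
    u <- (branch$knots[i + 1L, ] - branch$knots[i, ]) / dt
    lam <- seq(0, 1, length.out = n_probe)
    probes <- outer(rep(1, n_probe), branch$knots[i, ]) + outer(lam * dt, u)
    jn <- vapply(seq_len(n_probe), function(j)
      norm(phi_jacobian(phi, probes[j, ]) - diag(3L), type = "2"), 0)
    deps <- .eucl(eps[i + 1L, ] - eps[i, ])
    terms[i] <- 0.5 * (max(jn) * dt + deps)
  }
  structure(list(bound_value = max(terms), per_interval_terms = terms,
                 knot_spacing_delta = max(diff(branch$timestamps)),
                 n_probe = n_probe,
                 inputs_descriptor = phi$descriptor),
            class = "bound_report")
}

#' Comparable spline error bounds for zeroth- and first-order mapping
#'
#' Pure arithmetic form of the worst-case bounds that make the two
#' schemes comparable. With `M2`, `M3`, `M4` the maxima of
#' `|d^k f_j / dt^k|` over coordinates `j` (second and third derivatives
#' taken at the knots, fourth over the whole interval) of the transformed
#' curve `f = phi o c`, and `delta` the largest knot spacing, the
#' first-order (linear) spline satisfies
#'
#' \deqn{\max_t |f - g_0| \le \tfrac34 M_4 (\delta/2)^4
#'   + \tfrac32 (\delta/2)^2 M_3 (\delta/2)
#'   + \tfrac32 (\delta/2)^2 M_2,}
#'
#' and the cubic Hermite reconstruction of first-order mapping satisfies
#'
#' \deqn{\max_t |f - g_1| \le \tfrac{3}{4!} M_4 (\delta/2)^4.}
#'
#' The second bound is always at least as tight: it drops the `M2`/`M3`
#' terms entirely and shrinks the quartic coefficient by a factor 6.
#' Both are attained by a worst-case curve, so neither can be improved
#' in general.
#'
#' @param M2,M3,M4 non-negative derivative maxima (microns /
#'   micron^k along the arc-length parameter).
#' @param delta largest knot spacing, microns (> 0).
#' @return list with `bound0` and `bound1`, microns.
#' @examples
#' spline_error_bounds(M2 = 0, M3 = 0, M4 = 24, delta = 2) # 18 and 3
#' @export
spline_error_bounds <- function(M2, M3, M4, delta) {
  if (any(c(M2, M3, M4) < 0) || delta <= 0)
    stop("parameter error: derivative maxima must be >= 0 and delta > 0")
  h <- delta / 2
  bound0 <- 0.75 * M4 * h^4 + 1.5 * h^2 * M3 * h + 1.5 * h^2 * M2
  bound1 <- (3 / factorial(4)) * M4 * h^4
  list(bound0 = bound0, bound1 = bound1)
}

#' Estimate derivative maxima of a transformed curve
#'
#' Supplies the `M2`, `M3`, `M4` inputs of [spline_error_bounds()] for a
#' concrete branch and transformation by central finite differences of
#' `f = phi o c` along the arc-length parameter. Each knot interval is a
#' separate smooth piece (the source curve is piecewise linear), so the
#' stencils are confined to interval interiors, inset by two probe steps
#' from the knots where the composition is merely continuous.
#'
#' @param branch a `branch`.
#' @param phi a smooth `diffeo`.
#' @param probe_spacing stencil step along the parameter, microns; also
#'   the probe grid pitch. Halving it should move the estimates by little
#'   for smooth maps (a practical convergence check).
#' @return list `M2`, `M3`, `M4` (maxima over probes and coordinates)
#'   plus the `probe_spacing` used.
#' @export
estimate_curve_derivative_maxima <- function(branch, phi,
                                             probe_spacing = 0.25) {
  stopifnot(inherits(branch, "branch"), probe_spacing > 0)
  m <- nrow(branch$knots)
  M <- c(0, 0, 0)
  h <- probe_spacing
  for (i in seq_len(m - 1L)) {
    dt <- branch$timestamps[i + 1L] - branch$timestamps[i]
    if (dt <= 4 * h) next                    # interval too short to probe
    u <- (branch$knots[i + 1L, ] - branch$knots[i, ]) / dt
    s <- seq(2 * h, dt - 2 * h, by = h)
    if (length(s) < 1L) next
    # f on the 5-point stencils around every probe
    offs <- (-2):2
    sall <- as.vector(outer(offs * h, s, "+"))
    pts <- outer(rep(1, length(sall)), branch$knots[i, ]) + outer(sall, u)
    fall <- phi_apply(phi, pts)
    dim(fall) <- c(length(offs), length(s), 3L)
    d2 <- (fall[2L, , ] - 2 * fall[3L, , ] + fall[4L, , ]) / h^2
    d3 <- (-fall[1L, , ] + 2 * fall[2L, , ] - 2 * fall[4L, , ] +
             fall[5L, , ]) / (2 * h^3)
    d4 <- (fall[1L, , ] - 4 * fall[2L, , ] + 6 * fall[3L, , ] -
             4 * fall[4L, , ] + fall[5L, , ]) / h^4
    M <- pmax(M, c(max(abs(d2)), max(abs(d3)), max(abs(d4))))
  }
  if (all(M == 0) && m >= 2L && all(diff(branch$timestamps) <= 4 * h))
    stop("parameter error: probe grid degenerate for every interval; ",
         "reduce probe_spacing")
  list(M2 = M[1L], M3 = M[2L], M4 = M[3L], probe_spacing = probe_spacing)
}

#' @export
print.bound_report <- function(x, ...) {
  cat("zeroth-order mapping error bound:", format(x$bound_value), "um\n")
  cat("  max knot spacing:", format(x$knot_spacing_delta), "um;",
      x$n_probe, "probes per interval\n")
  invisible(x)
}
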