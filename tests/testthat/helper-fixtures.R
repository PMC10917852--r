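# Shared fixtures: hand-built traces, analytic test diffeomorphisms with
# exact derivatives, and brute-force oracles.

# straight path along x with n nodes, `step` microns apart
straight_trace <- function(n = 5, step = 5) {
  neuron_trace(data.frame(id = 1:n, structure_id = 0L,
                          x = (0:(n - 1)) * step, y = 0, z = 0,
                          radius = 1,
                          parent_id = c(-1L, 1:(n - 1))))
}

# Y-tree: root -> A (length 10), A -> leaf1 (5), A -> leaf2 (3)
y_trace <- function() {
  neuron_trace(data.frame(
    id = 1:4, structure_id = 0L,
    x = c(0, 10, 15, 10), y = c(0, 0, 0, 3), z = 0, radius = 1,
    parent_id = c(-1L, 1L, 2L, 2L)))
}

make_branch <- function(knots) {
  knots <- as.matrix(knots)
  structure(list(knots = knots,
                 timestamps = c(0, cumsum(sqrt(rowSums(diff(knots)^2)))),
                 origin_ids = seq_len(nrow(knots))),
            class = "branch")
}

# phi(x, y, z) = (x, y + x^2 / 100, z), exact derivatives
quad_diffeo <- function() {
  diffeomorphism(
    map = function(p) c(p[1], p[2] + p[1]^2 / 100, p[3]),
    jacobian = function(p) matrix(c(1, p[1] / 50, 0,
                                    0, 1, 0,
                                    0, 0, 1), 3, 3),
    hessian = function(p) {
      H <- array(0, c(3, 3, 3))
      H[2, 1, 1] <- 1 / 50
      H
    })
}

# phi_i(x) = (A x + b)_i + c_i * sin(w_i . x + p_i), exact J and H
sin_diffeo <- function(A = diag(3), b = c(0, 0, 0),
                       cc = c(3, 2, 1) / 10, W = diag(3) / 5,
                       ph = c(0, 1, 2)) {
  diffeomorphism(
    map = function(p) drop(A %*% p) + b + cc * sin(drop(W %*% p) + ph),
    jacobian = function(p) {
      A + diag(cc * cos(drop(W %*% p) + ph)) %*% W
    },
    hessian = function(p) {
      s <- sin(drop(W %*% p) + ph)
      H <- array(0, c(3, 3, 3))
      for (i in 1:3) H[i, , ] <- -cc[i] * s[i] * outer(W[i, ], W[i, ])
      H
    })
}

# a random, mildly nonlinear analytic diffeo (exact derivatives)
random_sin_diffeo <- function(strength = 0.2) {
  A <- diag(3) + matrix(runif(9, -0.1, 0.1), 3)
  if (det(A) <= 0) A <- diag(3)
  sin_diffeo(A = A, b = runif(3, -5, 5),
             cc = runif(3, 0, strength), W = matrix(runif(9, -0.3, 0.3), 3),
             ph = runif(3, 0, 2 * pi))
}

# arc-length parameterized helix and its exact jets
helix_point <- function(t, r = 10, h = 4) {
  s <- sqrt(r^2 + h^2)
  c(r * cos(t / s), r * sin(t / s), h * t / s)
}
helix_tangent <- function(t, r = 10, h = 4) {
  s <- sqrt(r^2 + h^2)
  c(-r * sin(t / s), r * cos(t / s), h) / s
}

# central finite-difference jets of a curve function at t
fd_jet <- function(curve_fn, t, k, h = 1e-3) {
  x0 <- curve_fn(t)
  out <- list(x0)
  if (k >= 1) out[[2]] <- (curve_fn(t + h) - curve_fn(t - h)) / (2 * h)
  if (k >= 2) out[[3]] <- (curve_fn(t + h) - 2 * x0 + curve_fn(t - h)) / h^2
  jet(t, out)
}

# exhaustive-coupling discrete Frechet oracle (branch-and-bound over all
# monotone couplings; exact)
frechet_bruteforce <- function(P, Q) {
  n <- nrow(P); m <- nrow(Q)
  d <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) d[i, j] <- sqrt(sum((P[i, ] - Q[j, ])^2))
  best <- Inf
  rec <- function(i, j, cur) {
    cur <- max(cur, d[i, j])
    if (cur >= best) return(invisible())
    if (i == n && j == m) {
      best <<- cur
      return(invisible())
    }
    if (i < n && j < m) rec(i + 1, j + 1, cur)
    if (i < n) rec(i + 1, j, cur)
    if (j < m) rec(i, j + 1, cur)
  }
  rec(1L, 1L, 0)
  best
}

max_rel_err <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  max(abs(a - b) / pmax(1, abs(b)))
}

jet_vec <- function(j) unlist(j$x)
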