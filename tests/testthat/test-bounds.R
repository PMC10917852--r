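test_that("the Jacobian bound vanishes for identity and pure translation", {
  br <- make_branch(rbind(c(0, 0, 0), c(5, 0, 0), c(5, 5, 0)))
  expect_equal(jacobian_error_bound(br, affine_diffeo(diag(3)))$bound_value,
               0, tolerance = 1e-12)
  shift <- affine_diffeo(diag(3), b = c(10, -20, 5))
  expect_equal(jacobian_error_bound(br, shift)$bound_value, 0,
               tolerance = 1e-12)
})

test_that("hand-evaluated Jacobian bound for the doubling map on one segment", {
  # Dphi = 2I so |Dphi - I| = 1; eps_i = x_i - 2 x_i = -x_i so
  # |eps_1 - eps_0| = L = 10; bound = (10 + 10)/2 = 10
  br <- make_branch(rbind(c(0, 0, 0), c(10, 0, 0)))
  rep10 <- jacobian_error_bound(br, affine_diffeo(diag(3) * 2))
  expect_equal(rep10$bound_value, 10, tolerance = 1e-12)
  # the measured zeroth-order error is 0 under this (affine) map: the
  # bound holds but is loose
  gt <- map_segment_ground_truth(c(0, 0, 0), c(10, 0, 0),
                                 affine_diffeo(diag(3) * 2))
  m0 <- map_segment_order0(c(0, 0, 0), c(10, 0, 0), affine_diffeo(diag(3) * 2))
  expect_lt(max(abs(m0$samples - gt$samples)), 1e-12)
})

test_that("n_probe below 2 is a parameter error", {
  br <- make_branch(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(jacobian_error_bound(br, affine_diffeo(diag(3)), n_probe = 1),
               "parameter error")
})

test_that("comparable spline bounds reproduce direct arithmetic", {
  expect_equal(spline_error_bounds(0, 0, 0, delta = 3),
               list(bound0 = 0, bound1 = 0))
  b <- spline_error_bounds(M2 = 0, M3 = 0, M4 = 24, delta = 2)
  expect_equal(b$bound0, 18)
  expect_equal(b$bound1, 3)
  expect_error(spline_error_bounds(-1, 0, 0, 1), "parameter error")
})

test_that("the first-order bound is always tighter, with ratio 1/6 in the pure-quartic limit", {
  set.seed(1)
  for (i in 1:50) {
    b <- spline_error_bounds(runif(1, 0, 5), runif(1, 0, 5),
                             runif(1, 0.1, 5), delta = runif(1, 0.1, 10))
    expect_lt(b$bound1, b$bound0)
  }
  b <- spline_error_bounds(1e-12, 1e-12, M4 = 2, delta = 1.5)
  expect_equal(b$bound1 / b$bound0, 1 / 6, tolerance = 1e-6)
})

test_that("derivative maxima of an affine image of a straight segment are ~0", {
  br <- make_branch(rbind(c(0, 0, 0), c(12, 0, 0)))
  A <- diag(3) * 1.3; A[2, 1] <- 0.5
  M <- estimate_curve_derivative_maxima(br, affine_diffeo(A), 0.25)
  expect_lt(M$M2, 1e-6)
  expect_lt(M$M3, 1e-6)
  expect_lt(M$M4, 1e-6)
})

test_that("derivative maxima of a sinusoidal composition match analytic values", {
  # f(t) = (t, sin t, 0) along c(t) = (t, 0, 0): all derivative maxima 1
  phi <- diffeomorphism(
    map = function(p) c(p[1], p[2] + sin(p[1]), p[3]),
    jacobian = function(p) matrix(c(1, cos(p[1]), 0, 0, 1, 0, 0, 0, 1), 3, 3))
  br <- make_branch(rbind(c(0, 0, 0), c(8, 0, 0)))
  M <- estimate_curve_derivative_maxima(br, phi, probe_spacing = 0.05)
  expect_equal(M$M2, 1, tolerance = 0.02)
  expect_equal(M$M3, 1, tolerance = 0.02)
  expect_equal(M$M4, 1, tolerance = 0.02)
  # halving the probe spacing moves the estimates by < 5%
  M2 <- estimate_curve_derivative_maxima(br, phi, probe_spacing = 0.025)
  expect_lt(abs(M2$M2 - M$M2) / M$M2, 0.05)
  expect_lt(abs(M2$M4 - M$M4) / M$M4, 0.05)
})

test_that("measured mapping errors respect all three bounds (soundness audit)", {
  set.seed(5)
  pairs <- list(
    list(br = make_branch(cbind(seq(0, 24, by = 8), 0, 0)),
         phi = sin_diffeo(cc = c(3, 2, 1), W = diag(3) / 2)),
    list(br = make_branch(rbind(c(0, 0, 0), c(6, 2, 0), c(10, 8, 3))),
         phi = sin_diffeo(cc = c(2, 2, 2), W = matrix(0.25, 3, 3))),
    list(br = decompose_branches(generate_trace(synthetic_trace_config(
      n_branches = 1, seed = 2)))$branches[[1L]],
         phi = random_sin_diffeo(strength = 2)))
  for (p in pairs) {
    br <- p$br; phi <- p$phi
    err <- c(0, 0)
    for (i in seq_len(nrow(br$knots) - 1L)) {
      gt <- map_segment_ground_truth(br$knots[i, ], br$knots[i + 1L, ], phi,
                                     spacing = 0.1)
      m0 <- map_segment_order0(br$knots[i, ], br$knots[i + 1L, ], phi,
                               spacing = 0.1)
      m1 <- map_segment_order1(br$knots[i, ], br$knots[i + 1L, ], phi,
                               spacing = 0.1)
      err[1L] <- max(err[1L], max(sqrt(rowSums((m0$samples - gt$samples)^2))))
      err[2L] <- max(err[2L], max(sqrt(rowSums((m1$samples - gt$samples)^2))))
    }
    jb <- jacobian_error_bound(br, phi, n_probe = 50)
    M <- estimate_curve_derivative_maxima(br, phi, probe_spacing = 0.05)
    sb <- spline_error_bounds(M$M2, M$M3, M$M4,
                              delta = max(diff(br$timestamps)))
    expect_lte(err[1L], jb$bound_value * 1.01)
    expect_lte(err[1L], sb$bound0 * 1.01)
    expect_lte(err[2L], sb$bound1 * 1.01)
    expect_lte(sb$bound1, sb$bound0)
  }
})
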