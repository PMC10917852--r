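test_that("ground truth under the identity samples the segment every 2 microns", {
  id <- affine_diffeo(diag(3))
  mc <- map_segment_ground_truth(c(0, 0, 0), c(5, 0, 0), id)
  expect_equal(mc$params, c(0, 2, 4, 5))
  expect_equal(mc$samples, cbind(c(0, 2, 4, 5), 0, 0), ignore_attr = TRUE)
})

test_that("all three schemes share endpoints and coincide under affine maps", {
  A <- matrix(c(1.5, 0.3, 0, -0.2, 1, 0.1, 0, 0.4, 0.9), 3, 3)
  phi <- affine_diffeo(A, b = c(10, -5, 2))
  x0 <- c(1, 2, 3); x1 <- c(11, 7, -1)
  gt <- map_segment_ground_truth(x0, x1, phi)
  m0 <- map_segment_order0(x0, x1, phi)
  m1 <- map_segment_order1(x0, x1, phi)
  for (m in list(gt, m0, m1)) {
    expect_equal(m$samples[1L, ], phi_apply(phi, x0), tolerance = 1e-12)
    expect_equal(m$samples[nrow(m$samples), ], phi_apply(phi, x1),
                 tolerance = 1e-12)
  }
  expect_lt(max(abs(m0$samples - gt$samples)), 1e-9)
  expect_lt(max(abs(m1$samples - gt$samples)), 1e-9)
})

test_that("quadratic map: images bend onto the parabola and errors match closed forms", {
  phi <- quad_diffeo()
  x0 <- c(0, 0, 0); x1 <- c(10, 0, 0)
  gt <- map_segment_ground_truth(x0, x1, phi, spacing = 0.5)
  # image of the straight line is y = x^2/100 exactly
  expect_equal(gt$samples[, 2L], gt$samples[, 1L]^2 / 100, tolerance = 1e-12)

  # zeroth order: chord under the parabola, max gap s(10-s)/100 = 0.25 at s=5
  m0 <- map_segment_order0(x0, x1, phi, spacing = 0.5)
  gaps <- sqrt(rowSums((m0$samples - gt$samples)^2))
  expect_equal(max(gaps), 0.25, tolerance = 1e-12)
  expect_equal(gt$params[which.max(gaps)], 5)

  # first order: the parabola is a cubic, so Hermite reconstruction is exact
  m1 <- map_segment_order1(x0, x1, phi, spacing = 0.5)
  err1 <- max(sqrt(rowSums((m1$samples - gt$samples)^2)))
  expect_lt(err1, 1e-9)
  expect_lt(err1, max(gaps))
})

test_that("mapped samples hit the transformed knots exactly for every scheme", {
  phi <- sin_diffeo(cc = c(2, 3, 1), W = diag(3) / 4)
  tr <- generate_trace(synthetic_trace_config(n_branches = 3, seed = 8))
  d <- decompose_branches(tr)
  br <- d$branches[[1L]]
  for (i in seq_len(nrow(br$knots) - 1L)) {
    x0 <- br$knots[i, ]; x1 <- br$knots[i + 1L, ]
    for (fn in list(map_segment_ground_truth, map_segment_order0,
                    map_segment_order1)) {
      mc <- fn(x0, x1, phi)
      expect_lt(sqrt(sum((mc$samples[1L, ] - phi_apply(phi, x0))^2)), 1e-9)
      expect_lt(sqrt(sum((mc$samples[nrow(mc$samples), ] -
                            phi_apply(phi, x1))^2)), 1e-9)
    }
  }
})

test_that("first-order endpoint tangents equal the Jacobian-transported chord", {
  phi <- sin_diffeo()
  x0 <- c(0, 0, 0); x1 <- c(8, 4, 2)
  u <- (x1 - x0) / sqrt(sum((x1 - x0)^2))
  m1 <- map_segment_order1(x0, x1, phi, spacing = 0.01)
  fd0 <- (m1$samples[2L, ] - m1$samples[1L, ]) /
    (m1$params[2L] - m1$params[1L])
  n <- nrow(m1$samples)
  fd1 <- (m1$samples[n, ] - m1$samples[n - 1L, ]) /
    (m1$params[n] - m1$params[n - 1L])
  expect_equal(fd0, drop(phi$jacobian(x0) %*% u), tolerance = 1e-3)
  expect_equal(fd1, drop(phi$jacobian(x1) %*% u), tolerance = 1e-3)
})

test_that("deviation from ground truth scales as delta^2 (order 0) and delta^4 (order 1)", {
  phi <- sin_diffeo(cc = c(3, 2, 1), W = diag(3) / 2, ph = c(0.3, 1, 2))
  deltas <- c(4, 2, 1, 0.5)
  errs <- vapply(deltas, function(dl) {
    knots <- cbind(seq(0, 20, by = dl), 0, 0)
    e <- c(0, 0)
    for (i in seq_len(nrow(knots) - 1L)) {
      gt <- map_segment_ground_truth(knots[i, ], knots[i + 1L, ], phi,
                                     spacing = dl / 20)
      m0 <- map_segment_order0(knots[i, ], knots[i + 1L, ], phi,
                               spacing = dl / 20)
      m1 <- map_segment_order1(knots[i, ], knots[i + 1L, ], phi,
                               spacing = dl / 20)
      e[1L] <- max(e[1L], max(sqrt(rowSums((m0$samples - gt$samples)^2))))
      e[2L] <- max(e[2L], max(sqrt(rowSums((m1$samples - gt$samples)^2))))
    }
    e
  }, c(0, 0))
  slope0 <- coef(lm(log(errs[1L, ]) ~ log(deltas)))[2L]
  slope1 <- coef(lm(log(errs[2L, ]) ~ log(deltas)))[2L]
  expect_lt(abs(slope0 - 2), 0.4)
  expect_lt(abs(slope1 - 4), 0.4)
})

test_that("map_trace under the identity reproduces the trace up to 2 um resampling", {
  tr <- generate_trace(synthetic_trace_config(n_branches = 3, seed = 13))
  id <- affine_diffeo(diag(3))
  out <- map_trace(tr, id, order = "gt")
  validate_trace(out)
  # every output node lies on the original polyline (distance 0 to within fp)
  expect_equal(trace_frechet(out, map_trace(tr, id, order = 0)), 0,
               tolerance = 1e-12)
  expect_equal(trace_frechet(out, map_trace(tr, id, order = 1)), 0,
               tolerance = 1e-9)
  # dense sampling: consecutive nodes at most 2 um apart
  expect_lte(max(decompose_branches(out)$branches[[1L]]$timestamps |>
                   diff()), 2 + 1e-9)
})

test_that("trace-level mapping is affine-exact for orders 0 and 1", {
  tr <- generate_trace(synthetic_trace_config(n_branches = 4, seed = 17))
  A <- diag(3) * 1.2; A[1, 2] <- 0.4
  phi <- affine_diffeo(A, b = c(-3, 2, 7))
  gt <- map_trace(tr, phi, "gt")
  expect_lt(trace_frechet(map_trace(tr, phi, 0), gt), 1e-9)
  expect_lt(trace_frechet(map_trace(tr, phi, 1), gt), 1e-9)
})

test_that("whole-trace mapping commutes with branch decomposition per segment", {
  tr <- y_trace()
  phi <- quad_diffeo()
  out <- map_trace(tr, phi, order = 1)
  d <- decompose_branches(tr)
  for (b in seq_along(d$branches)) {
    br <- d$branches[[b]]
    segs <- lapply(seq_len(nrow(br$knots) - 1L), function(i)
      map_segment_order1(br$knots[i, ], br$knots[i + 1L, ], phi)$samples)
    manual <- do.call(rbind, c(segs[1L], lapply(segs[-1L],
                                                function(s) s[-1L, ])))
    expect_equal(out$branch_samples[[b]], manual, tolerance = 1e-12)
  }
})
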