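test_that("zero curvature gives straight branches; generation is deterministic", {
  cfg <- synthetic_trace_config(n_branches = 1, nodes_per_branch = c(20, 20),
                                curvature_scale = 0, seed = 5)
  tr <- generate_trace(cfg)
  d <- decompose_branches(tr)
  br <- d$branches[[1L]]
  chord <- br$knots[nrow(br$knots), ] - br$knots[1L, ]
  sag <- max(apply(br$knots, 1L, function(p) {
    v <- p - br$knots[1L, ]
    sqrt(max(0, sum(v^2) - sum(v * chord)^2 / sum(chord^2)))
  }))
  expect_lt(sag / arc_length(br), 1e-6)
  expect_identical(generate_trace(cfg)$nodes, tr$nodes)
})

test_that("realized mean sampling period tracks the request within 10%", {
  periods <- vapply(1:20, function(s)
    mean_sampling_period(generate_trace(synthetic_trace_config(
      n_branches = 5, nodes_per_branch = c(10, 20), sampling_period = 10,
      seed = s))), 0)
  expect_lt(abs(mean(periods) - 10) / 10, 0.1)
})

test_that("generated traces always satisfy the trace invariants", {
  for (s in 1:10) {
    tr <- generate_trace(synthetic_trace_config(
      n_branches = 1 + s %% 5, seed = s,
      curvature_scale = 0.05, spatial_extent = 100))
    expect_silent(validate_trace(tr))
  }
})

test_that("sigma = 0 sweep leaves traces unchanged: zero error, matching morphometry", {
  tr <- generate_trace(synthetic_trace_config(n_branches = 2, seed = 6))
  res <- run_sigma_sweep(list(tr), sigmas = 0, seeds = 1)
  expect_equal(nrow(res), 2L)
  expect_lt(max(res$frechet), 1e-9)
  # zeroth order reproduces the identity bitwise, so its KS statistics
  # vanish exactly
  r0 <- res[res$method == "order0", ]
  expect_equal(unlist(r0[, c("ks_path_angle", "ks_branch_angle",
                             "ks_tortuosity", "ks_segment_length")]),
               c(0, 0, 0, 0), ignore_attr = TRUE)
  # first order agrees up to spline-evaluation roundoff; the morphometric
  # quantities themselves coincide to far below any biological signal
  tr0 <- center_trace(tr)
  phi <- random_diffeomorphism(random_diffeo_config(
    sigma = 0, grid_extent = max(abs(as.matrix(tr0$nodes[, c("x", "y", "z")]))) +
      500, seed = 1))
  m1 <- morphometry(map_trace(tr0, phi, "order1"))
  mg <- morphometry(map_trace(tr0, phi, "ground_truth"))
  expect_equal(sort(m1$path_angles), sort(mg$path_angles), tolerance = 1e-6)
  expect_equal(sort(m1$tortuosities), sort(mg$tortuosities), tolerance = 1e-6)
  expect_equal(sort(m1$segment_lengths), sort(mg$segment_lengths),
               tolerance = 1e-6)
})

test_that("sweep records are a pure function of configs and seeds", {
  tr <- generate_trace(synthetic_trace_config(n_branches = 2, seed = 14,
                                              spatial_extent = 100))
  r1 <- run_sigma_sweep(list(tr), sigmas = 320, seeds = 2)
  r2 <- run_sigma_sweep(list(tr), sigmas = 320, seeds = 2)
  expect_identical(r1, r2)
})

test_that("Frechet error grows with the sampling period at fixed sigma", {
  errs <- vapply(c(5, 25), function(period) {
    traces <- lapply(1:4, function(s) generate_trace(synthetic_trace_config(
      n_branches = 2, sampling_period = period, spatial_extent = 120,
      seed = 100 + s)))
    res <- run_sigma_sweep(traces, sigmas = 640, seeds = 1:4)
    median(res$frechet[res$method == "order0"])
  }, 0)
  expect_lt(errs[1L], errs[2L])
})

test_that("node removal under the identity map keeps every candidate node", {
  tr <- generate_trace(synthetic_trace_config(
    n_branches = 1, nodes_per_branch = c(30, 30), curvature_scale = 0.001,
    seed = 8))
  res <- run_node_removal_study(tr, affine_diffeo(diag(3)))
  expect_false(res$empty)
  expect_gt(res$n_candidates, 0)
  expect_equal(res$fraction_order0, 1)
  expect_equal(res$fraction_order1, 1)
})

test_that("a trace with no near-straight nodes reports the empty flag", {
  # zig-zag: every interior path angle is 90 degrees
  n <- 8
  zig <- neuron_trace(data.frame(
    id = 1:n, structure_id = 0L,
    x = cumsum(c(0, rep(5, n - 1))),
    y = rep(c(0, 5), length.out = n), z = 0, radius = 1,
    parent_id = c(-1L, 1:(n - 1))))
  res <- run_node_removal_study(zig, affine_diffeo(diag(3)))
  expect_true(res$empty)
  expect_equal(res$n_candidates, 0L)
})

test_that("first-order mapping keeps at least as many nodes under strong deformation", {
  wins <- 0L; total <- 0L
  for (s in 1:8) {
    tr <- generate_trace(synthetic_trace_config(
      n_branches = 1, nodes_per_branch = c(25, 25), curvature_scale = 0.002,
      sampling_period = 20, spatial_extent = 300, seed = 200 + s))
    tr <- center_trace(tr)
    pos <- as.matrix(tr$nodes[, c("x", "y", "z")])
    phi <- random_diffeomorphism(random_diffeo_config(
      sigma = 640, grid_extent = max(abs(pos)) + 500, seed = s))
    res <- run_node_removal_study(tr, phi)
    if (res$empty) next
    total <- total + 1L
    if (res$fraction_order1 >= res$fraction_order0) wins <- wins + 1L
  }
  expect_gt(total, 4L)
  expect_gte(wins / total, 0.5)
})
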