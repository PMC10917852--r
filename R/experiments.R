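#' Sigma-sweep mapping comparison
#'
#' The benchmark protocol for comparing zeroth- and first-order mapping:
#' for every trace and every momenta noise level `sigma`, center the
#' trace at the origin (mean of node positions), generate a random
#' diffeomorphism on a grid covering the trace plus a kernel-width
#' margin, map the trace with both schemes plus the dense ground truth
#' (2 micron upsampling of the source followed by point-wise transform),
#' and record the branch-matched discrete Frechet error and the KS
#' statistic of each morphometric quantity against ground truth, along
#' with the trace's mean inter-node spacing.
#'
#' @param traces list of `neuron_trace` objects.
#' @param sigmas noise levels, microns/time (the canonical sweep is
#'   `c(80, 160, 320, 640)`).
#' @param seeds one generator seed per trace (recycled); the same seed is
#'   reused across `sigmas` so the deformations at different severities
#'   are scaled versions of one another.
#' @param kernel_width,grid_spacing,n_timesteps passed to
#'   [random_diffeo_config()].
#' @param spacing dense sample pitch for mapping/ground truth, microns.
#' @return a data.frame with one row per (trace, sigma, method):
#'   `trace`, `trace_seed`, `sigma`, `method`, `frechet` (microns),
#'   `ks_path_angle`, `ks_branch_angle`, `ks_tortuosity`,
#'   `ks_segment_length`, `mean_sampling_period` (microns).
#' @export
run_sigma_sweep <- function(traces, sigmas = c(80, 160, 320, 640),
                            seeds = seq_along(traces),
                            kernel_width = 500, grid_spacing = 100,
                            n_timesteps = 10, spacing = 2) {
  seeds <- rep_len(seeds, length(traces))
  rows <- list()
  for (ti in seq_along(traces)) {
    tr <- center_trace(traces[[ti]])
    pos <- trace_positions(tr)
    extent <- max(abs(pos)) + kernel_width
    msp <- mean_sampling_period(tr)
    for (sg in sigmas) {
      phi <- random_diffeomorphism(random_diffeo_config(
        sigma = sg, grid_extent = extent, grid_spacing = grid_spacing,
        kernel_width = kernel_width, n_timesteps = n_timesteps,
        seed = seeds[ti]))
      gt <- map_trace(tr, phi, "ground_truth", spacing = spacing)
      gt_morph <- morphometry(gt)
      for (method in c("order0", "order1")) {
        mp <- map_trace(tr, phi, method, spacing = spacing)
        ks <- morph_ks(morphometry(mp), gt_morph)
        rows[[length(rows) + 1L]] <- data.frame(
          trace = ti, trace_seed = seeds[ti], sigma = sg, method = method,
          frechet = trace_frechet(mp, gt),
          ks_path_angle = ks[1L], ks_branch_angle = ks[2L],
          ks_tortuosity = ks[3L], ks_segment_length = ks[4L],
          mean_sampling_period = msp)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

morph_ks <- function(a, b) {
  one <- function(x, y) {
    if (!length(x) || !length(y)) return(NA_real_)
    ks_statistic(x, y)
  }
  c(one(a$path_angles, b$path_angles),
    one(a$branch_angles, b$branch_angles),
    one(a$tortuosities, b$tortuosities),
    one(a$segment_lengths, b$segment_lengths))
}

#' Mean distance between connected trace nodes
#'
#' The trace's average sampling period, the quantity against which
#' mapping error is stratified.
#'
#' @param trace a `neuron_trace`.
#' @return mean edge length, microns.
#' @export
mean_sampling_period <- function(trace) {
  nd <- trace$nodes
  p <- match(nd$parent_id, nd$id)
  h <- !is.na(p)
  pos <- trace_positions(trace)
  mean(.row_norms(pos[h, , drop = FALSE] - pos[p[h], , drop = FALSE]))
}

#' Node-removal downsampling study
#'
#' Estimates what fraction of trace nodes are redundant for mapped
#' morphology: every non-branching, non-terminal node whose path angle
#' exceeds `angle_threshold` degrees (i.e. the trace is nearly straight
#' there) is tentatively removed, the single parent-to-child segment is
#' mapped with each scheme, and the result is compared against the
#' ground-truth mapping of the original two-segment span. A node counts
#' as removable under a scheme if the discrete Frechet distance between
#' the two dense curves is at most `tol` (1 micron by default).
#'
#' @param trace a valid `neuron_trace`.
#' @param phi a `diffeo` defined over the trace.
#' @param angle_threshold candidate path-angle cutoff, degrees.
#' @param tol removability criterion on the discrete Frechet error,
#'   microns.
#' @param spacing dense sample pitch, microns.
#' @return list with `fraction_order0`, `fraction_order1` (fractions of
#'   candidates meeting `tol`; `NA` when there are no candidates),
#'   `n_candidates`, `empty` flag, and the per-candidate error table.
#' @export
run_node_removal_study <- function(trace, phi, angle_threshold = 170,
                                   tol = 1, spacing = 2) {
  validate_trace(trace)
  nd <- trace$nodes
  pos <- trace_positions(trace)
  pidx <- match(nd$parent_id, nd$id)
  n <- nrow(nd)
  nkids <- tabulate(pidx[!is.na(pidx)], nbins = n)
  cand <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(pidx[i]) || nkids[i] != 1L) next
    child <- which(!is.na(pidx) & pidx == i)
    v1 <- pos[pidx[i], ] - pos[i, ]
    v2 <- pos[child, ] - pos[i, ]
    ang <- acos(pmin(pmax(sum(v1 * v2) / (.eucl(v1) * .eucl(v2)), -1), 1)) *
      180 / pi
    if (ang > angle_threshold) cand <- c(cand, i)
  }
  if (!length(cand))
    return(list(fraction_order0 = NA_real_, fraction_order1 = NA_real_,
                n_candidates = 0L, empty = TRUE, errors = NULL))
  errs <- t(vapply(cand, function(i) {
    p <- pos[pidx[i], ]; m <- pos[i, ]
    ch <- which(!is.na(pidx) & pidx == i)
    cpos <- pos[ch, ]
    gt <- rbind(map_segment_ground_truth(p, m, phi, spacing)$samples,
                map_segment_ground_truth(m, cpos, phi, spacing)$samples[-1L, ,
                                                                        drop = FALSE])
    e0 <- discrete_frechet(map_segment_order0(p, cpos, phi, spacing)$samples, gt)
    e1 <- discrete_frechet(map_segment_order1(p, cpos, phi, spacing)$samples, gt)
    c(e0, e1)
  }, c(0, 0)))
  list(fraction_order0 = mean(errs[, 1L] <= tol),
       fraction_order1 = mean(errs[, 2L] <= tol),
       n_candidates = length(cand), empty = FALSE,
       errors = data.frame(node_id = nd$id[cand],
                           order0 = errs[, 1L], order1 = errs[, 2L]))
}
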