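#' Configuration for the synthetic trace generator
#'
#' Parameters of the random tree-structured traces used throughout the
#' test protocols as stand-ins for real reconstructions. Branches follow
#' an integrated random-walk tangent model: the heading persists and is
#' perturbed at each step, giving smoothly curving paths like axons
#' wending through tissue, discretized at a controllable sampling period.
#'
#' Defaults emulate a desk-scale cortical reconstruction: a handful of
#' branches, ~10 micron knot spacing (the regime where conventional
#' mapping is reported to stay accurate), gentle curvature, and a few
#' hundred microns of spatial extent.
#'
#' @param n_branches number of branches in the tree (>= 1).
#' @param nodes_per_branch length-2 range; each branch's knot count is
#'   drawn uniformly from it.
#' @param sampling_period mean knot spacing, microns; realized spacings
#'   get +/-30% uniform jitter.
#' @param curvature_scale heading perturbation per micron of path
#'   (1/micron); 0 gives straight branches.
#' @param spatial_extent half-width of the box the trace is kept inside,
#'   microns (headings are reflected inward at the walls).
#' @param seed integer; generation is a pure function of the config.
#' @return an object of class `synthetic_trace_config`.
#' @export
synthetic_trace_config <- function(n_branches = 3, nodes_per_branch = c(8, 20),
                                   sampling_period = 10,
                                   curvature_scale = 0.02,
                                   spatial_extent = 250, seed = 1) {
  stopifnot(n_branches >= 1, all(nodes_per_branch >= 2),
            sampling_period > 0, curvature_scale >= 0, spatial_extent > 0)
  structure(list(n_branches = as.integer(n_branches),
                 nodes_per_branch = as.integer(rep_len(nodes_per_branch, 2L)),
                 sampling_period = sampling_period,
                 curvature_scale = curvature_scale,
                 spatial_extent = spatial_extent,
                 seed = as.integer(seed)),
            class = "synthetic_trace_config")
}

#' Generate a random synthetic neuron trace
#'
#' Builds a rooted tree of smoothly curving branches under the model in
#' [synthetic_trace_config()]. The first branch starts at the origin;
#' each further branch sprouts from a uniformly chosen non-leaf node of
#' the structure built so far with a fresh random heading. The result
#' always satisfies the trace invariants (single root, acyclic, no
#' repeat positions).
#'
#' @param config a `synthetic_trace_config`.
#' @return a valid `neuron_trace`.
#' @examples
#' tr <- generate_trace(synthetic_trace_config(seed = 42))
#' tr
#' @export
generate_trace <- function(config) {
  stopifnot(inherits(config, "synthetic_trace_config"))
  .with_seed(config$seed, {
    ext <- config$spatial_extent
    rand_dir <- function() {
      v <- rnorm(3L)
      v / .eucl(v)
    }
    # sample() treats a scalar first argument as 1:n; avoid that trap
    pick <- function(v) v[1L + floor(runif(1L) * length(v)) %% length(v)]
    rint <- function(a, b) pick(seq.int(a, b))
    grow_branch <- function(start, heading, n_knots) {
      pts <- matrix(0, n_knots, 3L)
      pts[1L, ] <- start
      for (i in 2:n_knots) {
        step <- config$sampling_period * runif(1L, 0.7, 1.3)
        heading <- heading + config$curvature_scale * step * rnorm(3L)
        heading <- heading / .eucl(heading)
        cand <- pts[i - 1L, ] + step * heading
        # reflect the heading inward at the walls of the extent box
        for (a in 1:3) if (abs(cand[a]) > ext) {
          heading[a] <- -heading[a]
          cand <- pts[i - 1L, ] + step * heading
        }
        pts[i, ] <- cand
      }
      pts
    }
    n_first <- rint(config$nodes_per_branch[1L], config$nodes_per_branch[2L])
    all_pts <- grow_branch(c(0, 0, 0), rand_dir(), n_first)
    parent <- c(-1L, seq_len(n_first - 1L))
    is_leaf <- c(rep(FALSE, n_first - 1L), TRUE)
    for (b in seq_len(config$n_branches - 1L)) {
      attach_at <- pick(which(!is_leaf))
      nb <- rint(config$nodes_per_branch[1L], config$nodes_per_branch[2L])
      pts <- grow_branch(all_pts[attach_at, ], rand_dir(), nb)
      base <- nrow(all_pts)
      all_pts <- rbind(all_pts, pts[-1L, , drop = FALSE])
      parent <- c(parent, attach_at, base + seq_len(nb - 2L))
      is_leaf <- c(is_leaf, rep(FALSE, nb - 2L), TRUE)
    }
    nodes <- data.frame(id = seq_len(nrow(all_pts)),
                        structure_id = 0L,
                        x = all_pts[, 1L], y = all_pts[, 2L],
                        z = all_pts[, 3L],
                        radius = 1,
                        parent_id = parent)
    neuron_trace(nodes, metadata = paste0(
      "synthetic trace: seed=", config$seed,
      " branches=", config$n_branches,
      " sampling_period=", config$sampling_period))
  })
}
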