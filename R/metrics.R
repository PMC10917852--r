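#' Discrete Frechet distance between polylines
#'
#' Minimum over monotone couplings of the two point sequences of the
#' maximum coupled pairwise distance, computed by the standard dynamic
#' program over the `|P| x |Q|` distance grid. Symmetric; zero exactly
#' when the sequences traverse identical points in order; an upper bound
#' to the continuous Frechet distance.
#'
#' @param P,Q polylines as n x 3 matrices of row points (microns).
#' @return scalar distance, microns.
#' @examples
#' P <- cbind(0:3, 0, 0); Q <- cbind(0:3, 1, 0)
#' discrete_frechet(P, Q)  # 1
#' @export
discrete_frechet <- function(P, Q) {
  P <- as_polyline(P); Q <- as_polyline(Q)
  .frechet_dp(P, Q)
}

as_polyline <- function(m) {
  if (inherits(m, "mapped_curve")) m <- m$samples
  if (!is.matrix(m)) m <- matrix(as.numeric(m), ncol = 3L)
  if (nrow(m) == 0L) stop("parameter error: empty polyline")
  storage.mode(m) <- "double"
  m
}

#' Frechet distance between two mappings of the same trace
#'
#' The trace-level error of a mapped neuron is the maximum discrete
#' Frechet distance over corresponding branches. Correspondence is by
#' construction: both arguments must be mappings of the same source trace
#' (e.g. a scheme under test and the dense ground truth), so branch `i`
#' of one matches branch `i` of the other. Traces produced by
#' [map_trace()] carry their per-branch dense polylines; other traces are
#' decomposed on the fly.
#'
#' @param A,B `neuron_trace` objects mapped from a common source.
#' @return scalar distance, microns.
#' @export
trace_frechet <- function(A, B) {
  pa <- branch_polylines(A)
  pb <- branch_polylines(B)
  if (length(pa) != length(pb))
    stop("correspondence error: traces have ", length(pa), " and ",
         length(pb), " branches")
  max(vapply(seq_along(pa), function(i) discrete_frechet(pa[[i]], pb[[i]]),
             0))
}

branch_polylines <- function(tr) {
  if (!is.null(tr$branch_samples)) return(tr$branch_samples)
  lapply(decompose_branches(tr)$branches, `[[`, "knots")
}

#' Morphometric summary of a neuron trace
#'
#' The four distributional descriptors used to judge whether a mapping
#' preserved a neuron's shape statistics:
#'
#' * **path angles** (degrees): at every node with a parent and exactly
#'   one child, the angle between the node-to-parent and node-to-child
#'   directions, so a straight continuation scores 180 and a
#'   right-angle kink scores 90.
#' * **branch angles** (degrees): at every bifurcation, the angle between
#'   the child directions (all pairs when more than two children).
#' * **tortuosities** (>= 1): per decomposition branch, arc length over
#'   endpoint-to-endpoint Euclidean distance.
#' * **segment lengths** (microns): Euclidean length of every edge.
#'
#' All four are invariant to rigid motions of the trace.
#'
#' @param trace a valid `neuron_trace`.
#' @return an object of class `morphometry_summary`, a list of the four
#'   numeric vectors.
#' @export
morphometry <- function(trace) {
  validate_trace(trace)
  nd <- trace$nodes
  pos <- trace_positions(trace)
  pidx <- match(nd$parent_id, nd$id)
  n <- nrow(nd)
  kids <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(pidx[i]))
    kids[[pidx[i]]] <- c(kids[[pidx[i]]], i)
  angle_deg <- function(v1, v2) {
    n1 <- .eucl(v1); n2 <- .eucl(v2)
    if (n1 == 0 || n2 == 0)
      stop("degeneracy error: zero-length vector in angle computation")
    cosang <- sum(v1 * v2) / (n1 * n2)
    acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  path_angles <- numeric(0)
  branch_angles <- numeric(0)
  for (i in seq_len(n)) {
    ch <- kids[[i]]
    if (length(ch) == 1L && !is.na(pidx[i])) {
      path_angles <- c(path_angles,
                       angle_deg(pos[pidx[i], ] - pos[i, ],
                                 pos[ch, ] - pos[i, ]))
    } else if (length(ch) >= 2L) {
      prs <- utils::combn(ch, 2L)
      for (p in seq_len(ncol(prs)))
        branch_angles <- c(branch_angles,
                           angle_deg(pos[prs[1L, p], ] - pos[i, ],
                                     pos[prs[2L, p], ] - pos[i, ]))
    }
  }
  dec <- decompose_branches(trace)
  torts <- vapply(dec$branches, function(br) {
    chord <- .eucl(br$knots[nrow(br$knots), ] - br$knots[1L, ])
    if (chord == 0) return(NA_real_)
    arc_length(br) / chord
  }, 0)
  torts <- torts[!is.na(torts)]
  has_p <- !is.na(pidx)
  seg_len <- .row_norms(pos[has_p, , drop = FALSE] -
                          pos[pidx[has_p], , drop = FALSE])
  structure(list(path_angles = path_angles, branch_angles = branch_angles,
                 tortuosities = torts, segment_lengths = seg_len),
            class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat("morphometry:",
      length(x$path_angles), "path angles,",
      length(x$branch_angles), "branch angles,",
      length(x$tortuosities), "branch tortuosities,",
      length(x$segment_lengths), "segment lengths\n")
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Sup-norm distance between the empirical CDFs of two samples -- the
#' statistic used to score how far a mapped trace's morphometric
#' distribution drifted from ground truth. Only the statistic is
#' computed; use [stats::ks.test()] for a significance test.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return the statistic, in `[0, 1]`.
#' @examples
#' ks_statistic(c(1, 2, 3), c(1, 2, 4))  # 1/3
#' @export
ks_statistic <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b))
    stop("parameter error: empty sample")
  v <- sort(unique(c(sample_a, sample_b)))
  Fa <- vapply(v, function(q) mean(sample_a <= q), 0)
  Fb <- vapply(v, function(q) mean(sample_b <= q), 0)
  max(abs(Fa - Fb))
}

#' Paired comparison of mapping methods
#'
#' Convenience wrapper around the standard two-sided Wilcoxon signed-rank
#' test with Bonferroni correction across deformation severities, for
#' tables of per-trace errors.
#'
#' @param err_a,err_b paired error vectors (one entry per trace).
#' @param n_comparisons Bonferroni factor (number of sigma levels
#'   tested).
#' @return list with `p_value` (raw) and `p_adjusted`.
#' @export
paired_method_test <- function(err_a, err_b, n_comparisons = 1L) {
  ht <- stats::wilcox.test(err_a, err_b, paired = TRUE, exact = FALSE)
  list(p_value = ht$p.value,
       p_adjusted = min(1, ht$p.value * n_comparisons))
}
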