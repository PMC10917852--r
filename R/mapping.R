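# arc-length sample parameters for a segment of length L: every `spacing`
# microns from 0, clamped below L, then the endpoint itself
segment_params <- function(L, spacing = 2) {
  s <- seq(0, L, by = spacing)
  s <- s[s < L]
  c(s, L)
}

# evaluate the cubic Hermite interpolant on [0, L] with endpoint values
# y0, y1 (3-vectors) and derivatives d0, d1 (w.r.t. the source parameter)
hermite_eval <- function(s, L, y0, y1, d0, d1) {
  tau <- s / L
  h00 <- (1 + 2 * tau) * (1 - tau)^2
  h10 <- tau * (1 - tau)^2
  h01 <- tau^2 * (3 - 2 * tau)
  h11 <- tau^2 * (tau - 1)
  outer(h00, y0) + outer(h10 * L, d0) + outer(h01, y1) + outer(h11 * L, d1)
}

new_mapped_curve <- function(samples, params, method, spline = NULL) {
  structure(list(samples = samples, params = params, method = method,
                 spline = spline),
            class = "mapped_curve")
}

#' Map a single line segment under a diffeomorphism
#'
#' The three mapping schemes for the segment from `x0` to `x1` (length
#' `L = |x1 - x0|`), all evaluated on the identical arc-length parameter
#' grid `{0, spacing, 2*spacing, ...} < L` plus `L`:
#'
#' * **ground truth** (`map_segment_ground_truth`): sample the source
#'   segment every `spacing` microns and push each sample through `phi` —
#'   the image of the piecewise-linear curve itself.
#' * **zeroth order** (`map_segment_order0`): transform only the
#'   endpoints and interpolate linearly between the images — what
#'   conventional trace-mapping pipelines do.
#' * **first order** (`map_segment_order1`): additionally transform the
#'   unit chord `u = (x1 - x0)/L` through the Jacobian at each endpoint
#'   and reconstruct with the cubic Hermite interpolant matching
#'   `phi(x0), phi(x1), Dphi(x0)u, Dphi(x1)u`.
#'
#' All three agree at the endpoints; under affine maps all three agree
#' everywhere.
#'
#' @param x0,x1 segment endpoints (3-vectors, microns), distinct.
#' @param phi a `diffeo` whose domain contains the segment.
#' @param spacing sample pitch along the source parameter, microns.
#' @return a `mapped_curve`: `samples` (n x 3), `params` (source
#'   arc-length values), `method`, and for the spline methods the
#'   interpolant data.
#' @export
map_segment_ground_truth <- function(x0, x1, phi, spacing = 2) {
  x0 <- as.numeric(x0); x1 <- as.numeric(x1)
  L <- .eucl(x1 - x0)
  if (L <= 0) stop("degeneracy error: x0 and x1 coincide")
  s <- segment_params(L, spacing)
  src <- outer(rep(1, length(s)), x0) + outer(s / L, x1 - x0)
  new_mapped_curve(phi_apply(phi, src), s, "ground_truth")
}

#' @rdname map_segment_ground_truth
#' @export
map_segment_order0 <- function(x0, x1, phi, spacing = 2) {
  x0 <- as.numeric(x0); x1 <- as.numeric(x1)
  L <- .eucl(x1 - x0)
  if (L <= 0) stop("degeneracy error: x0 and x1 coincide")
  y0 <- phi_apply(phi, x0); y1 <- phi_apply(phi, x1)
  s <- segment_params(L, spacing)
  samples <- outer(rep(1, length(s)), y0) + outer(s / L, y1 - y0)
  new_mapped_curve(samples, s, "order0",
                   spline = list(L = L, y = rbind(y0, y1)))
}

#' @rdname map_segment_ground_truth
#' @export
map_segment_order1 <- function(x0, x1, phi, spacing = 2) {
  x0 <- as.numeric(x0); x1 <- as.numeric(x1)
  L <- .eucl(x1 - x0)
  if (L <= 0) stop("degeneracy error: x0 and x1 coincide")
  u <- (x1 - x0) / L
  y0 <- phi_apply(phi, x0); y1 <- phi_apply(phi, x1)
  d0 <- drop(phi_jacobian(phi, x0) %*% u)
  d1 <- drop(phi_jacobian(phi, x1) %*% u)
  s <- segment_params(L, spacing)
  new_mapped_curve(hermite_eval(s, L, y0, y1, d0, d1), s, "order1",
                   spline = list(L = L, y = rbind(y0, y1),
                                 d = rbind(d0, d1)))
}

map_segment <- function(x0, x1, phi, order, spacing = 2) {
  switch(order,
         ground_truth = map_segment_ground_truth(x0, x1, phi, spacing),
         order0 = map_segment_order0(x0, x1, phi, spacing),
         order1 = map_segment_order1(x0, x1, phi, spacing),
         stop("unknown mapping order: ", order))
}

#' Map a whole neuron trace under a diffeomorphism
#'
#' Trace-level pipeline: decompose the trace into non-bifurcating
#' branches, map every segment with the requested scheme on a dense
#' arc-length grid (default every 2 microns), chain the dense samples
#' within each branch, and reassemble the branches into a tree by fusing
#' the junction copies. The output trace's nodes are the dense samples;
#' its topology is isomorphic to the input's. Ground truth corresponds to
#' upsampling the original piecewise-linear trace to the sample pitch and
#' transforming every point.
#'
#' @param trace a valid `neuron_trace` inside `phi`'s domain.
#' @param phi a `diffeo`.
#' @param order `"0"`/`0` (zeroth), `"1"`/`1` (first), or
#'   `"ground_truth"`/`"gt"`.
#' @param spacing dense sample pitch, microns.
#' @return a `neuron_trace` whose extra element `branch_samples` holds
#'   the per-branch dense polylines (n x 3 matrices, in decomposition
#'   order), used for branch-matched Frechet comparison.
#' @examples
#' tr <- read_swc(c("1 0 0 0 0 1 -1", "2 0 10 0 0 1 1", "3 0 10 8 0 1 2"))
#' phi <- affine_diffeo(diag(3) * 2)
#' mapped <- map_trace(tr, phi, order = 1)
#' @export
map_trace <- function(trace, phi, order = 1, spacing = 2) {
  order <- normalize_order(order)
  dec <- decompose_branches(trace)
  nd <- trace$nodes
  id_struct <- function(id) nd$structure_id[match(id, nd$id)]
  id_radius <- function(id) nd$radius[match(id, nd$id)]

  branch_samples <- vector("list", length(dec$branches))
  branch_meta <- vector("list", length(dec$branches))
  for (b in seq_along(dec$branches)) {
    br <- dec$branches[[b]]
    m <- nrow(br$knots)
    seg_curves <- lapply(seq_len(m - 1L), function(i)
      map_segment(br$knots[i, ], br$knots[i + 1L, ], phi, order, spacing))
    pieces <- lapply(seq_along(seg_curves), function(i) {
      s <- seg_curves[[i]]$samples
      if (i > 1L) s[-1L, , drop = FALSE] else s   # knot shared with prev seg
    })
    dense <- do.call(rbind, pieces)
    # dense row index of each original knot
    counts <- vapply(pieces, nrow, 0L)
    knot_rows <- c(1L, cumsum(counts))
    # structure/radius carried from the segment's starting knot
    seg_of_row <- rep.int(seq_len(m - 1L), counts)
    seg_of_row[1L] <- 1L
    branch_samples[[b]] <- dense
    branch_meta[[b]] <- list(
      knot_rows = knot_rows,
      struct = id_struct(br$origin_ids)[seg_of_row],
      radius = id_radius(br$origin_ids)[seg_of_row])
  }

  # assemble: branch 1 chains from the root; each later branch attaches
  # its second dense sample to the already-emitted junction node
  out_id_of_origin <- new.env(parent = emptyenv())
  rows <- vector("list", length(branch_samples))
  next_id <- 1L
  for (b in seq_along(branch_samples)) {
    dense <- branch_samples[[b]]
    meta <- branch_meta[[b]]
    br <- dec$branches[[b]]
    first_origin <- as.character(br$origin_ids[1L])
    if (b == 1L) {
      start_row <- 1L
      parent0 <- -1L
    } else {
      parent0 <- get(first_origin, envir = out_id_of_origin)
      prev <- rows_pos[[parent0]]
      dev <- .eucl(dense[1L, ] - prev)
      if (dev > 1e-9)
        stop("consistency error: junction node ", br$origin_ids[1L],
             " mapped ", format(dev), " um apart across branches")
      start_row <- 2L
    }
    n_new <- nrow(dense) - start_row + 1L
    ids <- seq.int(next_id, length.out = n_new)
    parents <- c(if (b == 1L) -1L else parent0, ids[-n_new])
    rows[[b]] <- data.frame(
      id = ids,
      structure_id = meta$struct[start_row:nrow(dense)],
      x = dense[start_row:nrow(dense), 1L],
      y = dense[start_row:nrow(dense), 2L],
      z = dense[start_row:nrow(dense), 3L],
      radius = meta$radius[start_row:nrow(dense)],
      parent_id = parents)
    # register output ids and positions of original knots for later branches
    for (j in seq_along(meta$knot_rows)) {
      r <- meta$knot_rows[j]
      if (r >= start_row || b == 1L) {
        oid <- as.character(br$origin_ids[j])
        if (!exists(oid, envir = out_id_of_origin))
          assign(oid, ids[r - start_row + 1L], envir = out_id_of_origin)
      }
    }
    if (b == 1L) rows_pos <- list()
    for (i in seq_len(n_new))
      rows_pos[[ids[i]]] <- dense[start_row + i - 1L, ]
    next_id <- next_id + n_new
  }
  out <- neuron_trace(do.call(rbind, rows),
                      metadata = c(trace$metadata,
                                   paste0("mapped with neurojet, order=",
                                          order, ", spacing=", spacing)))
  out$branch_samples <- branch_samples
  out
}

normalize_order <- function(order) {
  o <- as.character(order)
  switch(o,
         "0" = "order0", "order0" = "order0",
         "1" = "order1", "order1" = "order1",
         "gt" = "ground_truth", "ground_truth" = "ground_truth",
         stop("unknown mapping order: ", o))
}
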