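#' Decompose a neuron trace into non-bifurcating branches
#'
#' Splits a tree-shaped trace into simple curves by recursively removing
#' the root-to-leaf path with the longest arc length: the first branch is
#' the longest root-to-leaf path, and the procedure recurses on the
#' subtrees left hanging off already-extracted branches, each new branch
#' starting at a copy of its junction node. Every tree edge lands in
#' exactly one branch; junction nodes are the only duplicated knots.
#'
#' Each branch carries its knots, cumulative arc-length timestamps
#' (`t[1] = 0`, increments equal to segment lengths), and the originating
#' node ids. Ties between equally long root-to-leaf paths go to the path
#' whose leaf has the smaller node id, making the decomposition
#' deterministic.
#'
#' @param trace a valid `neuron_trace`.
#' @return an object of class `branch_decomposition`: a list with
#'   `branches` (list of `branch` objects, each with `knots` (m x 3
#'   matrix), `timestamps`, `origin_ids`), `junction_map` (for every node
#'   id copied into several branches, a data.frame of `(branch, knot)`
#'   positions), and the originating `trace`.
#' @examples
#' tr <- read_swc(c("1 0 0 0 0 1 -1", "2 0 10 0 0 1 1",
#'                  "3 0 10 5 0 1 2", "4 0 10 -3 0 1 2"))
#' d <- decompose_branches(tr)
#' length(d$branches)              # 2: root..longest leaf, then the spur
#' @export
decompose_branches <- function(trace) {
  validate_trace(trace)
  nd <- trace$nodes
  n <- nrow(nd)
  pos <- trace_positions(trace)
  idx_of_id <- function(ids) match(ids, nd$id)
  parent_idx <- match(nd$parent_id, nd$id)   # NA at root
  children <- vector("list", n)
  for (i in seq_len(n)) {
    p <- parent_idx[i]
    if (!is.na(p)) children[[p]] <- c(children[[p]], i)
  }
  # edge length node -> parent
  elen <- rep(0, n)
  has_p <- !is.na(parent_idx)
  elen[has_p] <- .row_norms(pos[has_p, , drop = FALSE] -
                              pos[parent_idx[has_p], , drop = FALSE])

  # farthest leaf (by arc length) from `start` descending only into `kids`;
  # ties broken by smaller leaf id
  farthest_leaf <- function(start, kids) {
    best_leaf <- NA_integer_; best_dist <- -Inf
    stack <- lapply(kids, function(k) list(node = k, d = elen[k]))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ch <- children[[cur$node]]
      if (!length(ch)) {
        better <- cur$d > best_dist ||
          (cur$d == best_dist && nd$id[cur$node] < nd$id[best_leaf])
        if (better) { best_leaf <- cur$node; best_dist <- cur$d }
      } else {
        for (k in ch)
          stack[[length(stack) + 1L]] <- list(node = k, d = cur$d + elen[k])
      }
    }
    best_leaf
  }

  root <- which(nd$parent_id == -1L)
  branches <- list()
  queue <- list(list(start = root, kids = children[[root]]))
  while (length(queue)) {
    task <- queue[[1L]]; queue <- queue[-1L]
    if (!length(task$kids)) next
    leaf <- farthest_leaf(task$start, task$kids)
    # path start..leaf via parent pointers
    path <- leaf
    while (path[1L] != task$start) path <- c(parent_idx[path[1L]], path)
    on_path <- logical(n); on_path[path] <- TRUE
    knots <- pos[path, , drop = FALSE]
    ts <- c(0, cumsum(.row_norms(diff(knots))))
    branches[[length(branches) + 1L]] <- structure(
      list(knots = knots, timestamps = ts, origin_ids = nd$id[path]),
      class = "branch")
    # remaining subtrees, enqueued in knot order then ascending child id
    for (node in path) {
      rem <- if (node == task$start) setdiff(task$kids, path)
             else setdiff(children[[node]], path)
      if (length(rem)) {
        rem <- rem[order(nd$id[rem])]
        queue[[length(queue) + 1L]] <- list(start = node, kids = rem)
      }
    }
  }
  # junction map: node ids present in >= 2 branches
  occ <- do.call(rbind, lapply(seq_along(branches), function(b) {
    data.frame(id = branches[[b]]$origin_ids, branch = b,
               knot = seq_along(branches[[b]]$origin_ids))
  }))
  dup_ids <- unique(occ$id[duplicated(occ$id)])
  junction_map <- occ[occ$id %in% dup_ids, , drop = FALSE]
  rownames(junction_map) <- NULL
  structure(list(branches = branches, junction_map = junction_map,
                 trace = trace),
            class = "branch_decomposition")
}

#' Total arc length of a branch or trace
#'
#' @param x a `branch`, `branch_decomposition`, or `neuron_trace`.
#' @return arc length in microns (for a decomposition, the sum over
#'   branches, which equals the tree's total edge length since junctions
#'   copy points, not edges).
#' @export
arc_length <- function(x) {
  if (inherits(x, "branch")) return(x$timestamps[length(x$timestamps)])
  if (inherits(x, "branch_decomposition"))
    return(sum(vapply(x$branches, arc_length, 0)))
  if (inherits(x, "neuron_trace")) {
    nd <- x$nodes
    p <- match(nd$parent_id, nd$id)
    h <- !is.na(p)
    pos <- trace_positions(x)
    return(sum(.row_norms(pos[h, , drop = FALSE] - pos[p[h], , drop = FALSE])))
  }
  stop("unsupported type")
}

#' Reassemble mapped branches into a neuron trace
#'
#' Inverse of [decompose_branches()] after per-branch mapping: replaces
#' each branch's knots with its mapped counterpart and fuses the junction
#' copies back into single nodes, preserving the original tree topology
#' and node ids. Because every copy of a junction node is the image of the
#' same point under the same map, the copies must coincide; a discrepancy
#' beyond `tol` signals a non-function transformation (or a bug) and is an
#' error, not something to average away.
#'
#' @param decomposition a `branch_decomposition`.
#' @param mapped_knots list (one per branch) of m x 3 matrices with the
#'   same knot count as the corresponding branch.
#' @param tol junction agreement tolerance in microns.
#' @return a `neuron_trace` with the original ids, parents, structure ids
#'   and radii, and the mapped positions.
#' @export
reassemble <- function(decomposition, mapped_knots, tol = 1e-9) {
  stopifnot(inherits(decomposition, "branch_decomposition"))
  brs <- decomposition$branches
  if (length(mapped_knots) != length(brs))
    stop("consistency error: ", length(mapped_knots),
         " replacement lists for ", length(brs), " branches")
  trace <- decomposition$trace
  nd <- trace$nodes
  newpos <- matrix(NA_real_, nrow(nd), 3L)
  for (b in seq_along(brs)) {
    mk <- as.matrix(mapped_knots[[b]])
    if (nrow(mk) != nrow(brs[[b]]$knots))
      stop("consistency error: branch ", b, " expects ",
           nrow(brs[[b]]$knots), " knots, got ", nrow(mk))
    rows <- match(brs[[b]]$origin_ids, nd$id)
    seen <- !is.na(newpos[rows, 1L])
    if (any(seen)) {
      dev <- .row_norms(newpos[rows[seen], , drop = FALSE] -
                          mk[seen, , drop = FALSE])
      if (any(dev > tol))
        stop("consistency error: junction node ",
             nd$id[rows[seen][which.max(dev)]],
             " mapped to positions ", format(max(dev)),
             " um apart across branches")
    }
    newpos[rows, ] <- mk
  }
  nd$x <- newpos[, 1L]; nd$y <- newpos[, 2L]; nd$z <- newpos[, 3L]
  neuron_trace(nd, trace$metadata)
}

#' @export
print.branch_decomposition <- function(x, ...) {
  cat("branch_decomposition:", length(x$branches), "branches,",
      "total arc length", format(arc_length(x)), "um\n")
  invisible(x)
}
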