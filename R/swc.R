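#' Construct a neuron trace
#'
#' A `neuron_trace` is the in-memory form of an SWC reconstruction: a node
#' table (one row per trace point) plus the free-form comment header. The
#' node table must describe a rooted tree: ids unique, every `parent_id`
#' either `-1` (the single root) or an existing id, no cycles, and no node
#' sharing its exact position with its parent (repeat trace points make the
#' arc-length parameterization of a branch degenerate and are rejected, the
#' same exclusion applied when curating real reconstructions).
#'
#' @param nodes data.frame with columns `id`, `structure_id`, `x`, `y`,
#'   `z`, `radius`, `parent_id`. Positions and radii are in microns.
#'   `structure_id` and `radius` are passed through untouched; mapping
#'   ignores them.
#' @param metadata character vector of header comment lines (without the
#'   leading `#`).
#' @return An object of class `neuron_trace`.
#' @seealso [read_swc()], [write_swc()], [decompose_branches()]
#' @export
neuron_trace <- function(nodes, metadata = character()) {
  stopifnot(is.data.frame(nodes))
  req <- c("id", "structure_id", "x", "y", "z", "radius", "parent_id")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols))
    stop("nodes is missing columns: ", paste(missing_cols, collapse = ", "))
  nodes <- nodes[, req]
  nodes$id <- as.integer(nodes$id)
  nodes$structure_id <- as.integer(nodes$structure_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  rownames(nodes) <- NULL
  obj <- structure(list(nodes = nodes, metadata = as.character(metadata)),
                   class = "neuron_trace")
  validate_trace(obj)
  obj
}

#' Validate the tree structure of a neuron trace
#'
#' Checks the SWC tree invariants and errors with a descriptive message on
#' the first violation: duplicate ids, dangling parent references,
#' multiple roots or none, cycles, and consecutive repeat positions
#' (a node at exactly its parent's coordinates).
#'
#' @param trace a `neuron_trace`.
#' @return `trace`, invisibly.
#' @export
validate_trace <- function(trace) {
  nd <- trace$nodes
  if (nrow(nd) == 0L) stop("structure error: trace has no nodes")
  if (anyDuplicated(nd$id))
    stop("structure error: duplicate node id ",
         nd$id[duplicated(nd$id)][1L])
  roots <- which(nd$parent_id == -1L)
  if (length(roots) != 1L)
    stop("structure error: expected exactly one root, found ",
         length(roots))
  known <- nd$parent_id == -1L | nd$parent_id %in% nd$id
  if (!all(known))
    stop("structure error: parent id ", nd$parent_id[!known][1L],
         " of node ", nd$id[!known][1L], " not present")
  # follow parent pointers; a cycle never reaches the root
  idx_of <- match(nd$parent_id, nd$id)       # NA at the root
  n <- nrow(nd)
  depth <- rep.int(NA_integer_, n)
  depth[roots] <- 0L
  for (i in seq_len(n)) {
    if (!is.na(depth[i])) next
    chain <- i
    j <- i
    repeat {
      j <- idx_of[j]
      if (is.na(j)) break                    # hit root
      if (!is.na(depth[j])) break            # hit resolved node
      if (j %in% chain)
        stop("structure error: cycle involving node id ", nd$id[j])
      chain <- c(chain, j)
      if (length(chain) > n)
        stop("structure error: cycle detected")
    }
    base <- if (is.na(j)) 0L else depth[j]
    depth[rev(chain)] <- base + seq_along(chain)
  }
  # repeat trace nodes: child exactly on top of its parent
  child <- which(!is.na(idx_of))
  if (length(child)) {
    p <- idx_of[child]
    same <- nd$x[child] == nd$x[p] & nd$y[child] == nd$y[p] &
      nd$z[child] == nd$z[p]
    if (any(same))
      stop("repeat-node error: node ", nd$id[child[same][1L]],
           " duplicates the position of its parent ",
           nd$id[p[same][1L]])
  }
  invisible(trace)
}

#' Read a neuron trace from SWC
#'
#' Parses the standard 7-column SWC format: `#` comment lines followed by
#' whitespace-separated rows `id type x y z radius parent`. The comment
#' header is preserved in `metadata` and node order is preserved. The tree
#' invariants are enforced at read time (see [neuron_trace()]).
#'
#' @param source path to an SWC file, a connection, or a character vector
#'   of lines.
#' @return a validated `neuron_trace`.
#' @examples
#' swc <- c("# toy", "1 0 0 0 0 1 -1", "2 0 5 0 0 1 1", "3 0 5 4 0 1 2")
#' tr <- read_swc(swc)
#' tr$nodes
#' @export
read_swc <- function(source) {
  lines <- if (is.character(source) && length(source) > 1L) source
           else if (is.character(source) && !file.exists(source) &&
                    grepl("\n", source)) strsplit(source, "\n")[[1L]]
           else readLines(source)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  metadata <- sub("^\\s*#\\s?", "", lines[is_comment])
  data_idx <- which(!is_comment & !is_blank)
  if (!length(data_idx)) stop("parse error: no data rows in SWC input")
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7L))
    stop("parse error at line ", data_idx[which(nf != 7L)[1L]],
         ": expected 7 whitespace-separated fields, got ",
         nf[nf != 7L][1L])
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  bad <- which(apply(m, 1L, function(r) any(is.na(r))))
  if (length(bad))
    stop("parse error at line ", data_idx[bad[1L]],
         ": non-numeric field")
  nodes <- data.frame(id = as.integer(m[, 1L]),
                      structure_id = as.integer(m[, 2L]),
                      x = m[, 3L], y = m[, 4L], z = m[, 5L],
                      radius = m[, 6L],
                      parent_id = as.integer(m[, 7L]))
  neuron_trace(nodes, metadata)
}

#' Write a neuron trace to SWC
#'
#' Emits metadata lines as `#` comments followed by one 7-column row per
#' node, positions printed with 9 significant digits so that
#' `read_swc(write_swc(tr))` reproduces the node table.
#'
#' @param trace a valid `neuron_trace`.
#' @param sink file path or connection; if `NULL` the lines are returned
#'   as a character vector.
#' @return the emitted lines, invisibly when written to `sink`.
#' @export
write_swc <- function(trace, sink = NULL) {
  validate_trace(trace)
  nd <- trace$nodes
  fmt <- function(v) sprintf("%.17g", v)   # exact double round trip
  rows <- paste(nd$id, nd$structure_id,
                vapply(nd$x, fmt, ""), vapply(nd$y, fmt, ""),
                vapply(nd$z, fmt, ""), vapply(nd$radius, fmt, ""),
                nd$parent_id)
  out <- c(if (length(trace$metadata)) paste("#", trace$metadata), rows)
  if (is.null(sink)) return(out)
  writeLines(out, sink)
  invisible(out)
}

#' @export
print.neuron_trace <- function(x, ...) {
  nd <- x$nodes
  n_leaf <- sum(!(nd$id %in% nd$parent_id))
  cat("neuron_trace:", nrow(nd), "nodes,", n_leaf, "leaves\n")
  if (length(x$metadata)) cat("metadata:", length(x$metadata), "line(s)\n")
  invisible(x)
}

# positions as an n x 3 matrix
trace_positions <- function(trace) {
  as.matrix(trace$nodes[, c("x", "y", "z")])
}

#' Center a trace at the origin
#'
#' Translates all node positions so their mean is the origin, the
#' normalization applied before mapping under generated deformations.
#'
#' @param trace a `neuron_trace`.
#' @return the centered `neuron_trace`.
#' @export
center_trace <- function(trace) {
  pos <- trace_positions(trace)
  ctr <- colMeans(pos)
  trace$nodes$x <- trace$nodes$x - ctr[1L]
  trace$nodes$y <- trace$nodes$y - ctr[2L]
  trace$nodes$z <- trace$nodes$z - ctr[3L]
  trace
}
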