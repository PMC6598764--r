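## NetworkSkeleton: node positions plus node-index segment pairs, with
## per-segment lengths and unit orientations derived from the geometry.

#' Construct a network skeleton
#'
#' @param nodes numeric matrix (n x 3) of node positions (um).
#' @param segments integer matrix (m x 2) of 1-based node index pairs.
#' @return object of class `network_skeleton` with fields `nodes`,
#'   `segments`, `lengths` (um) and `orientations` (unit row vectors).
#' @export
network_skeleton <- function(nodes, segments) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  segments <- as.matrix(segments)
  storage.mode(segments) <- "integer"
  if (ncol(nodes) != 3) stop("nodes must be an n x 3 matrix")
  if (ncol(segments) != 2) stop("segments must be an m x 2 matrix")
  if (any(segments < 1L) || any(segments > nrow(nodes)))
    stop("segment references a node index out of range")
  d <- nodes[segments[, 2], , drop = FALSE] - nodes[segments[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("zero-length segment")
  structure(list(nodes = nodes, segments = segments, lengths = len,
                 orientations = d / len),
            class = "network_skeleton")
}

#' @export
print.network_skeleton <- function(x, ...) {
  cat(sprintf("network_skeleton: %d nodes, %d segments, total length %.1f um\n",
              nrow(x$nodes), nrow(x$segments), sum(x$lengths)))
  invisible(x)
}

#' Read a network skeleton from JSON
#'
#' Schema: an object with `"nodes"` (list of `[x, y, z]` positions in um)
#' and `"segments"` (list of 1-based `[i, j]` node index pairs). Lengths and
#' orientations are recomputed from the node positions on load.
#'
#' @param path path to a `.json` skeleton file.
#' @return a [network_skeleton].
#' @export
read_skeleton <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(dat$nodes) || is.null(dat$segments))
    stop("skeleton JSON must contain 'nodes' and 'segments'")
  network_skeleton(dat$nodes, dat$segments)
}

#' Write a network skeleton to JSON
#' @param skeleton a [network_skeleton].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(skeleton, path) {
  stopifnot(inherits(skeleton, "network_skeleton"))
  jsonlite::write_json(list(nodes = skeleton$nodes,
                            segments = skeleton$segments),
                       path, digits = NA)
  invisible(path)
}
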