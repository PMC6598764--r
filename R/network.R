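## Anisotropy of sinusoid / bile-canaliculi network skeletons: the
## length-weighted nematic tensor of segment orientations,
##   N = (3/2) * sum_i l_i (e_i e_i^T - I/3) / sum_i l_i,
## and its largest-eigenvalue axis as the locally preferred direction.

#' Nematic anisotropy tensor of a network skeleton
#'
#' @param skeleton a [network_skeleton].
#' @param segment_idx optional subset of segment indices.
#' @return 3 x 3 `nematic_tensor`.
#' @export
skeleton_nematic_tensor <- function(skeleton,
                                    segment_idx = seq_len(nrow(skeleton$segments))) {
  if (length(segment_idx) == 0) stop("no segments selected")
  axis_nematic_tensor(skeleton$orientations[segment_idx, , drop = FALSE],
                      skeleton$lengths[segment_idx])
}

## clip segment [p, q] to the ball (center, radius); returns NULL when the
## intersection is empty, otherwise the clipped endpoints
clip_segment_to_ball <- function(p, q, center, radius) {
  d <- q - p
  f <- p - center
  a <- sum(d * d)
  b <- 2 * sum(f * d)
  cc <- sum(f * f) - radius^2
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NULL)
  s <- sqrt(disc)
  t0 <- max(0, (-b - s) / (2 * a))
  t1 <- min(1, (-b + s) / (2 * a))
  if (t1 <= t0) return(NULL)
  list(p = p + t0 * d, q = p + t1 * d)
}

#' Local preferred axis of a network around a point
#'
#' Restricts the skeleton to segments whose midpoint lies within `radius` of
#' `point` (segments crossing the ball boundary are clipped to it and their
#' lengths recomputed), computes the length-weighted nematic tensor of the
#' restriction, and returns its largest-eigenvalue axis and eigenvalue.
#'
#' @param skeleton a [network_skeleton].
#' @param point length-3 query position (um).
#' @param radius neighborhood radius (um); default 20, approximately one
#'   hepatocyte diameter.
#' @param degeneracy_tol eigenvalue-gap threshold for flagging a degenerate
#'   preferred axis; default 0.05.
#' @return `NULL` when no segments fall in the ball, else a list with
#'   `axis` (unit length-3), `weight` (largest eigenvalue), `degenerate`
#'   and `n_segments`.
#' @export
local_network_axis <- function(skeleton, point, radius = 20,
                               degeneracy_tol = 0.05) {
  stopifnot(radius > 0)
  point <- as.numeric(point)
  p <- skeleton$nodes[skeleton$segments[, 1], , drop = FALSE]
  q <- skeleton$nodes[skeleton$segments[, 2], , drop = FALSE]
  mid <- (p + q) / 2
  d2 <- rowSums(sweep(mid, 2, point)^2)
  sel <- which(d2 <= radius^2)
  if (length(sel) == 0) return(NULL)
  seg_axes <- matrix(0, length(sel), 3)
  seg_len <- numeric(length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    cl <- clip_segment_to_ball(p[i, ], q[i, ], point, radius)
    if (is.null(cl)) { # midpoint inside but numerically tangent; keep as-is
      cl <- list(p = p[i, ], q = q[i, ])
    }
    d <- cl$q - cl$p
    seg_len[k] <- sqrt(sum(d^2))
    seg_axes[k, ] <- d / seg_len[k]
  }
  keep <- seg_len > 1e-9
  if (!any(keep)) return(NULL)
  N <- axis_nematic_tensor(seg_axes[keep, , drop = FALSE], seg_len[keep])
  e <- eigen(unclass(N), symmetric = TRUE)
  list(axis = canonical_axis(e$vectors[, 1]),
       weight = e$values[1],
       degenerate = (e$values[1] - e$values[2]) < degeneracy_tol,
       n_segments = sum(keep))
}

#' Count dead-end nodes of a skeleton
#'
#' Nodes used by exactly one segment; a simple branching-defect summary for
#' perturbed-network scenarios.
#'
#' @param skeleton a [network_skeleton].
#' @return integer count.
#' @export
count_dead_ends <- function(skeleton) {
  deg <- tabulate(skeleton$segments, nbins = nrow(skeleton$nodes))
  sum(deg == 1L)
}
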