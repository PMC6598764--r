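## Per-cell biaxial nematic polarity. The labeled cell surface is radially
## projected onto a unit sphere about the volumetric center; the nematic
## tensor of a membrane domain is the solid-angle-weighted second moment of
## the projected triangle directions,
##
##   N = (3/2) * sum_{i in marker} A_i (n_i n_i^T - I/3) / sum_{i in marker} A_i,
##
## a symmetric traceless 3x3 tensor. Its eigen-system defines the bipolar
## axis a1 (largest eigenvalue sigma1) and the ring axis a2 (smallest,
## sigma2), with sigma2 <= sigma3 <= sigma1 and sigma1+sigma2+sigma3 = 0.

#' Triangles belonging to a membrane domain
#'
#' A triangle belongs to the domain of a label when at least two of its
#' three vertices carry that label.
#'
#' @param mesh a [labeled_mesh].
#' @param label `"apical"`, `"basal"`, `"lateral"` or `"unlabeled"`.
#' @return integer vector of triangle indices (possibly empty).
#' @export
select_marker_triangles <- function(mesh, label) {
  code <- label_code(label)
  hit <- matrix(mesh$labels[mesh$triangles] == code, ncol = 3)
  which(rowSums(hit) >= 2)
}

#' Radial spherical projection of a cell surface
#'
#' Projects every vertex onto the unit sphere about the cell's volumetric
#' center and computes, per triangle, the spherical (solid-angle) area `A_i`
#' and the unit direction `n_i` of the spherical-triangle centroid. The
#' projection assumes the mesh is star-convex with respect to its center;
#' triangles whose signed solid angle is non-positive violate that
#' assumption and are counted in `n_violations` (their absolute area is
#' used). For a closed star-convex mesh the areas sum to 4*pi.
#'
#' @param mesh a [labeled_mesh].
#' @param marker_label label whose triangle set (see
#'   [select_marker_triangles()]) is stored as `marker_mask`; default
#'   `"apical"`.
#' @return object of class `projected_triangles` with fields `areas`
#'   (steradians), `directions` (m x 3 unit rows), `marker_mask`,
#'   `n_violations` and `total_area`.
#' @export
spherical_projection <- function(mesh, marker_label = "apical") {
  rel <- sweep(mesh$vertices, 2, mesh$center)
  r <- sqrt(rowSums(rel^2))
  if (any(r < 1e-9))
    stop("degenerate projection: vertex coincides with the cell center")
  u <- rel / r
  a <- u[mesh$triangles[, 1], , drop = FALSE]
  b <- u[mesh$triangles[, 2], , drop = FALSE]
  c <- u[mesh$triangles[, 3], , drop = FALSE]
  sa <- triangle_solid_angle(a, b, c)
  n_violations <- sum(sa <= 0)
  if (n_violations > 0)
    warning(n_violations, " triangle(s) violate star-convexity about the center")
  structure(list(areas = abs(sa),
                 directions = unit_rows(a + b + c),
                 marker_mask = select_marker_triangles(mesh, marker_label),
                 n_violations = n_violations,
                 total_area = sum(abs(sa))),
            class = "projected_triangles")
}

#' Nematic tensor of a projected membrane domain
#'
#' Solid-angle-weighted nematic tensor over the marker triangle set, with
#' the normalization taken over the marker set so that an ideal bipolar
#' pattern yields sigma1 = 1 regardless of the marker's area fraction.
#'
#' @param proj a `projected_triangles` object from [spherical_projection()].
#' @param mask triangle indices to use; defaults to `proj$marker_mask`.
#' @return 3 x 3 symmetric traceless matrix of class `nematic_tensor`.
#' @export
nematic_tensor <- function(proj, mask = proj$marker_mask) {
  if (length(mask) == 0)
    stop("no triangles carry the requested marker")
  A <- proj$areas[mask]
  n <- proj$directions[mask, , drop = FALSE]
  M <- crossprod(n * A, n) / sum(A)     # sum A n n^T / sum A
  N <- 1.5 * M - 0.5 * diag(3)
  N <- (N + t(N)) / 2
  structure(N, class = c("nematic_tensor", "matrix"))
}

#' Nematic tensor of a set of weighted axes
#'
#' Shared kernel for segment- and cell-based nematic tensors:
#' `(3/2) * sum_i w_i (e_i e_i^T - I/3) / W`.
#'
#' @param axes n x 3 matrix of unit axes.
#' @param weights per-axis non-negative weights.
#' @param normalize divide by the total weight (default); if `FALSE` the
#'   unnormalized weighted sum is returned.
#' @return 3 x 3 symmetric traceless matrix of class `nematic_tensor`.
#' @export
axis_nematic_tensor <- function(axes, weights = rep(1, nrow(rbind(axes))),
                                normalize = TRUE) {
  axes <- rbind(axes)
  W <- sum(weights)
  M <- crossprod(axes * weights, axes)
  N <- 1.5 * (M - W * diag(3) / 3)
  if (normalize) N <- N / W
  N <- (N + t(N)) / 2
  structure(N, class = c("nematic_tensor", "matrix"))
}

## canonical sign for a stored axis: non-negative z, ties broken by y then x
canonical_axis <- function(v, tol = 1e-12) {
  s <- if (abs(v[3]) > tol) sign(v[3])
       else if (abs(v[2]) > tol) sign(v[2])
       else sign(v[1])
  if (s < 0) -v else v
}

#' Eigen-axes and weights of a nematic tensor
#'
#' Diagonalizes a symmetric traceless nematic tensor. With eigenvalues
#' ordered sigma2 <= sigma3 <= sigma1, the bipolar axis `a1` belongs to
#' sigma1 (largest), the ring axis `a2` to sigma2 (smallest), and
#' `a3 = a1 x a2`. Axes are sign-free; the stored representative has a
#' non-negative third component (ties broken by the second, then first).
#' An axis is flagged degenerate when its eigenvalue gap to the middle
#' eigenvalue is below `degeneracy_tol`.
#'
#' @param N a `nematic_tensor` (or any symmetric 3 x 3 matrix).
#' @param degeneracy_tol eigenvalue-gap threshold; default 0.05.
#' @return object of class `polarity_axes`: list with `axes` (3 x 3 matrix,
#'   rows a1, a2, a3), `sigma` (length 3: sigma1, sigma2, sigma3) and
#'   `degenerate` (logical length 3).
#' @export
polarity_axes <- function(N, degeneracy_tol = 0.05) {
  e <- eigen(unclass(N), symmetric = TRUE)   # values in decreasing order
  sigma <- c(e$values[1], e$values[3], e$values[2])
  a1 <- canonical_axis(e$vectors[, 1])
  a2 <- canonical_axis(e$vectors[, 3])
  a3 <- canonical_axis(as.numeric(cross_rows(a1, a2)))
  deg <- c(e$values[1] - e$values[2] < degeneracy_tol,   # a1 vs middle
           e$values[2] - e$values[3] < degeneracy_tol,   # a2 vs middle
           FALSE)
  deg[3] <- deg[1] || deg[2]
  structure(list(axes = rbind(a1 = a1, a2 = a2, a3 = a3),
                 sigma = sigma, degenerate = deg),
            class = "polarity_axes")
}

#' @export
print.polarity_axes <- function(x, ...) {
  cat(sprintf("polarity_axes: sigma1 = %.3f%s, sigma2 = %.3f%s\n",
              x$sigma[1], if (x$degenerate[1]) " (degenerate)" else "",
              x$sigma[2], if (x$degenerate[2]) " (degenerate)" else ""))
  cat(sprintf("  a1 = (%.3f, %.3f, %.3f)  a2 = (%.3f, %.3f, %.3f)\n",
              x$axes[1, 1], x$axes[1, 2], x$axes[1, 3],
              x$axes[2, 1], x$axes[2, 2], x$axes[2, 3]))
  invisible(x)
}

#' Biaxial polarity of one labeled cell mesh
#'
#' Convenience wrapper: spherical projection, nematic tensor of the
#' requested membrane domain, and its eigen-axes.
#'
#' @param mesh a [labeled_mesh].
#' @param label membrane label; default `"apical"`.
#' @param degeneracy_tol passed to [polarity_axes()].
#' @return a `polarity_axes` object.
#' @export
cell_polarity <- function(mesh, label = "apical", degeneracy_tol = 0.05) {
  proj <- spherical_projection(mesh, marker_label = label)
  polarity_axes(nematic_tensor(proj), degeneracy_tol = degeneracy_tol)
}

## ---- Mollweide projection ----

## solve 2 theta + sin(2 theta) = pi sin(phi) by Newton iteration
mollweide_theta <- function(phi) {
  theta <- phi
  at_pole <- abs(abs(phi) - pi / 2) < 1e-12
  for (it in 1:50) {
    f <- 2 * theta + sin(2 * theta) - pi * sin(phi)
    fp <- 2 + 2 * cos(2 * theta)
    step <- ifelse(fp < 1e-12, 0, f / fp)
    theta <- theta - step
    if (max(abs(step)) < 1e-13) break
  }
  theta[at_pole] <- sign(phi[at_pole]) * pi / 2
  theta
}

#' Mollweide map coordinates of the apical membrane domain
#'
#' Builds the cell-intrinsic map frame: the basal bipolar axis `b1` is the
#' pole axis, and the zero meridian passes through the apical bipolar axis
#' `a1`, which therefore appears vertically in the center of the map. Each
#' apical vertex is radially projected onto the unit sphere and mapped to
#' equal-area Mollweide coordinates with map half-width `2 * sqrt(2)`.
#'
#' @param mesh a [labeled_mesh].
#' @param apical `polarity_axes` of the apical domain.
#' @param basal `polarity_axes` of the basal domain.
#' @return data.frame with columns `vertex`, `lon`, `lat` (radians), `x`, `y`.
#' @export
mollweide_coordinates <- function(mesh, apical, basal) {
  if (apical$degenerate[1] || basal$degenerate[1])
    stop("map frame requires non-degenerate bipolar axes a1 and b1")
  a1 <- apical$axes[1, ]; b1 <- basal$axes[1, ]
  if (axis_angle_deg(a1, b1) < 1)
    stop("frame degeneracy: apical and basal bipolar axes are parallel")
  ez <- b1 / sqrt(sum(b1^2))
  ex <- a1 - sum(a1 * ez) * ez
  ex <- ex / sqrt(sum(ex^2))
  ey <- as.numeric(cross_rows(ez, ex))
  idx <- vertices_with_label(mesh, "apical")
  rel <- sweep(mesh$vertices[idx, , drop = FALSE], 2, mesh$center)
  u <- unit_rows(rel)
  lon <- atan2(u %*% ey, u %*% ex)
  lat <- asin(pmin(1, pmax(-1, u %*% ez)))
  theta <- mollweide_theta(as.numeric(lat))
  data.frame(vertex = idx,
             lon = as.numeric(lon), lat = as.numeric(lat),
             x = 2 * sqrt(2) / pi * as.numeric(lon) * cos(theta),
             y = sqrt(2) * sin(theta))
}

#' Mollweide coordinates of sphere points
#'
#' Maps longitude/latitude pairs (radians) to Mollweide `(x, y)`.
#'
#' @param lon,lat numeric vectors (radians); latitude in `[-pi/2, pi/2]`.
#' @return matrix with columns `x`, `y`.
#' @export
mollweide_xy <- function(lon, lat) {
  theta <- mollweide_theta(lat)
  cbind(x = 2 * sqrt(2) / pi * lon * cos(theta), y = sqrt(2) * sin(theta))
}

## ---- apical-basal axis cross-correlation ----

#' Alignment table of apical and basal polarity axes
#'
#' For each pair among (a1,b1), (a1,b2), (a2,b1), (a2,b2), computes the
#' nematic alignment parameter S (see [alignment_parameter()]) over cells
#' whose two axes in the pair are both non-degenerate. When `groups` is
#' given (e.g. one label per animal), S is computed per group and the
#' across-group mean and standard deviation are reported.
#'
#' @param cells list of [cell_record] objects with `apical` and `basal`
#'   polarity axes.
#' @param groups optional group label per cell.
#' @return data.frame with columns `pair`, `S`, `n` and, with groups,
#'   `mean_S`, `sd_S`, `n_groups`.
#' @export
axis_cross_correlation <- function(cells, groups = NULL) {
  pairs <- list(c("a1", "b1"), c("a1", "b2"), c("a2", "b1"), c("a2", "b2"))
  apical_idx <- c(a1 = 1L, a2 = 2L)
  basal_idx <- c(b1 = 1L, b2 = 2L)
  rows <- lapply(pairs, function(p) {
    ia <- apical_idx[[p[1]]]; ib <- basal_idx[[p[2]]]
    ok <- vapply(cells, function(cl) {
      !is.null(cl$apical) && !is.null(cl$basal) &&
        !cl$apical$degenerate[ia] && !cl$basal$degenerate[ib]
    }, TRUE)
    if (sum(ok) < 2)
      stop("fewer than 2 cells with non-degenerate axes for pair ",
           paste(p, collapse = "-"))
    E <- t(vapply(cells[ok], function(cl) cl$apical$axes[ia, ], numeric(3)))
    G <- t(vapply(cells[ok], function(cl) cl$basal$axes[ib, ], numeric(3)))
    out <- data.frame(pair = paste(p, collapse = "-"),
                      S = alignment_parameter(E, G), n = sum(ok))
    if (!is.null(groups)) {
      g <- groups[ok]
      per <- vapply(split(seq_along(g), g), function(i)
        alignment_parameter(E[i, , drop = FALSE], G[i, , drop = FALSE]), 0)
      out$mean_S <- mean(per)
      out$sd_S <- stats::sd(per)
      out$n_groups <- length(per)
    }
    out
  })
  do.call(rbind, rows)
}
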