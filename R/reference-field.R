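## Lobule-level reference system. Vein surfaces are converted to point
## charges (one per triangle, strength proportional to relative triangle
## area, +1 net on the central vein, -1 net on the portal vein). The scalar
## field chi(r) = sum_i q_i / |r - r_i| is the Green's-function
## superposition, and its gradient J = grad(chi), normalized to unit length,
## provides the local CV-PV reference direction.

#' Point charges from central- and portal-vein meshes
#'
#' One charge per triangle, placed at the triangle centroid, with strength
#' `q_i = +- A_i / sum_j A_j` (positive for the central vein, negative for
#' the portal vein), so each vein carries net charge +-1. Zero-area
#' triangles are dropped with a warning.
#'
#' @param cv_mesh,pv_mesh lists with `vertices` (n x 3, um) and `triangles`
#'   (m x 3, 1-based); a [labeled_mesh] works too.
#' @return object of class `charge_set`: list with `positions` (n x 3),
#'   `charges`, `vein` (factor `"CV"`/`"PV"`).
#' @export
build_charges <- function(cv_mesh, pv_mesh) {
  one_vein <- function(mesh, sign, tag) {
    v <- as.matrix(mesh$vertices)
    f <- as.matrix(mesh$triangles)
    if (nrow(f) < 1) stop("empty ", tag, " mesh")
    v1 <- v[f[, 1], , drop = FALSE]
    v2 <- v[f[, 2], , drop = FALSE]
    v3 <- v[f[, 3], , drop = FALSE]
    area <- 0.5 * sqrt(rowSums(cross_rows(v2 - v1, v3 - v1)^2))
    keep <- area > 1e-12
    if (!any(keep)) stop("all ", tag, " triangles are degenerate")
    if (!all(keep))
      warning("dropping ", sum(!keep), " zero-area triangle(s) from ", tag)
    area <- area[keep]
    centers <- (v1[keep, , drop = FALSE] + v2[keep, , drop = FALSE] +
                v3[keep, , drop = FALSE]) / 3
    list(positions = centers, charges = sign * area / sum(area),
         vein = rep(tag, length(area)))
  }
  cv <- one_vein(cv_mesh, +1, "CV")
  pv <- one_vein(pv_mesh, -1, "PV")
  structure(list(positions = rbind(cv$positions, pv$positions),
                 charges = c(cv$charges, pv$charges),
                 vein = factor(c(cv$vein, pv$vein), levels = c("CV", "PV"))),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("charge_set: %d charges (CV net %+.3f, PV net %+.3f)\n",
              length(x$charges),
              sum(x$charges[x$vein == "CV"]),
              sum(x$charges[x$vein == "PV"])))
  invisible(x)
}

check_exclusion <- function(points, charges, exclusion_radius) {
  for (i in seq_len(nrow(points))) {
    d2 <- rowSums(sweep(charges$positions, 2, points[i, ])^2)
    j <- which.min(d2)
    if (d2[j] < exclusion_radius^2)
      stop(sprintf(paste0("point (%.2f, %.2f, %.2f) is within %.2g um of ",
                          "charge %d (%s vein); singular region"),
                   points[i, 1], points[i, 2], points[i, 3],
                   exclusion_radius, j, as.character(charges$vein[j])))
  }
}

#' Evaluate the scalar reference field chi
#'
#' `chi(r) = sum_i q_i / |r - r_i|`. Negative values indicate closeness to
#' the portal vein, positive values closeness to the central vein.
#'
#' @param points n x 3 matrix of evaluation positions (um).
#' @param charges a [build_charges()] `charge_set`.
#' @param exclusion_radius minimum allowed distance to any charge (um);
#'   default 2. Points inside it raise an error naming the charge.
#' @return numeric vector of field values (1/um).
#' @export
evaluate_chi <- function(points, charges, exclusion_radius = 2) {
  points <- rbind(points)
  check_exclusion(points, charges, exclusion_radius)
  ## pairwise inverse distances: points x charges
  d2 <- outer(rowSums(points^2), rep(1, nrow(charges$positions))) +
    outer(rep(1, nrow(points)), rowSums(charges$positions^2)) -
    2 * points %*% t(charges$positions)
  d2[d2 < 0] <- 0
  as.numeric((1 / sqrt(d2)) %*% charges$charges)
}

#' Reference direction J = grad(chi)
#'
#' Analytic gradient of the Green's-function superposition,
#' `grad(chi)(r) = sum_i q_i (r_i - r) / |r - r_i|^3`, returned normalized
#' to unit length together with its raw magnitude. Points where the
#' gradient magnitude is below `stagnation_tol` are stagnation points: the
#' direction is set to `NA` and flagged.
#'
#' @inheritParams evaluate_chi
#' @param stagnation_tol magnitude below which the direction is undefined.
#' @return list with `J` (n x 3 unit rows, `NA` at stagnation points),
#'   `magnitude`, `stagnant` (logical).
#' @export
reference_direction <- function(points, charges, exclusion_radius = 2,
                                stagnation_tol = 1e-14) {
  points <- rbind(points)
  check_exclusion(points, charges, exclusion_radius)
  n <- nrow(points)
  J <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    rel <- sweep(charges$positions, 2, points[i, ])   # r_i - r
    d <- sqrt(rowSums(rel^2))
    J[i, ] <- colSums(rel * (charges$charges / d^3))
  }
  mag <- sqrt(rowSums(J^2))
  stagnant <- mag < stagnation_tol
  Ju <- J / mag
  Ju[stagnant, ] <- NA_real_
  list(J = Ju, magnitude = mag, stagnant = stagnant)
}

#' Trace a field line of the reference field
#'
#' Fixed-step Euler integration of the unit direction field, for
#' visualization export.
#'
#' @param start length-3 starting position (um).
#' @param charges a `charge_set`.
#' @param step step length (um); default 1.
#' @param n_steps maximum number of steps.
#' @param exclusion_radius stop when the line enters this distance of a
#'   charge; default 2 um.
#' @return matrix of polyline positions (k x 3).
#' @export
trace_field_line <- function(start, charges, step = 1, n_steps = 500,
                             exclusion_radius = 2) {
  pos <- matrix(as.numeric(start), 1, 3)
  path <- matrix(NA_real_, n_steps + 1, 3)
  path[1, ] <- pos
  k <- 1
  for (i in seq_len(n_steps)) {
    mind <- min(sqrt(rowSums(sweep(charges$positions, 2, pos[1, ])^2)))
    if (mind <= exclusion_radius) break
    g <- reference_direction(pos, charges, exclusion_radius = 0)
    if (g$stagnant[1]) break
    pos <- pos + step * g$J
    k <- k + 1
    path[k, ] <- pos
  }
  path[seq_len(k), , drop = FALSE]
}
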