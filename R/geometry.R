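## Low-level vector geometry shared by all modules. Positions are in
## micrometers, in a right-handed coordinate system.

#' Normalize rows of a matrix to unit length
#'
#' @param x numeric matrix (n x 3) of row vectors.
#' @return matrix of the same shape with unit rows.
#' @keywords internal
unit_rows <- function(x) {
  x <- rbind(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("cannot normalize a zero vector")
  x / nrm
}

#' Row-wise cross product
#' @param a,b matrices (n x 3) or length-3 vectors.
#' @keywords internal
cross_rows <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `angle` radians about the (not necessarily unit)
#' vector `axis`.
#'
#' @param axis length-3 numeric vector.
#' @param angle rotation angle in radians.
#' @return 3 x 3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- as.numeric(axis) / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Signed solid angles of spherical triangles
#'
#' Solid angle subtended at the origin by triangles whose vertices lie on
#' the unit sphere, via the van Oosterom--Strackee formula. The sign follows
#' the triangle orientation (positive for counterclockwise seen from
#' outside).
#'
#' @param a,b,c matrices (n x 3) of unit vertex vectors, one triangle per row.
#' @return numeric vector of signed solid angles (steradians).
#' @export
triangle_solid_angle <- function(a, b, c) {
  a <- rbind(a); b <- rbind(b); c <- rbind(c)
  num <- rowSums(a * cross_rows(b, c))
  den <- 1 + rowSums(a * b) + rowSums(b * c) + rowSums(a * c)
  2 * atan2(num, den)
}

#' Geodesic icosphere mesh
#'
#' Triangulated sphere obtained by repeated 4-fold subdivision of a regular
#' icosahedron with projection back onto the sphere; `subdivisions = s`
#' yields `20 * 4^s` outward-oriented triangles.
#'
#' @param subdivisions non-negative integer.
#' @param radius sphere radius (micrometers).
#' @return list with `vertices` (n x 3) and `triangles` (m x 3, 1-based).
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  stopifnot(subdivisions >= 0, radius > 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- unit_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- mid_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- verts[i, ] + verts[j, ]
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      i <- f[k, 1]; j <- f[k, 2]; l <- f[k, 3]
      a <- midpoint(i, j); b <- midpoint(j, l); c <- midpoint(l, i)
      nf[4 * k - 3, ] <- c(i, a, c)
      nf[4 * k - 2, ] <- c(j, b, a)
      nf[4 * k - 1, ] <- c(l, c, b)
      nf[4 * k, ] <- c(a, b, c)
    }
    v <- verts
    f <- nf
  }
  ## enforce outward orientation (positive solid angle from the center)
  sa <- triangle_solid_angle(v[f[, 1], , drop = FALSE],
                             v[f[, 2], , drop = FALSE],
                             v[f[, 3], , drop = FALSE])
  flip <- sa < 0
  if (any(flip)) f[flip, ] <- f[flip, c(1, 3, 2), drop = FALSE]
  dimnames(v) <- NULL
  storage.mode(f) <- "integer"
  list(vertices = v * radius, triangles = f)
}

#' Run an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed`, so generator functions can take an
#' optional `seed` argument without disturbing the caller's RNG stream.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## angle between two axes (sign-free), degrees
axis_angle_deg <- function(u, v) {
  d <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, d)) * 180 / pi
}
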