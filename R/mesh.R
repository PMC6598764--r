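## LabeledSurfaceMesh: per-cell triangulated surface with per-vertex
## membrane labels (apical / basal / lateral / unlabeled).

#' Membrane label codes
#'
#' Integer codes used on disk and in memory for per-vertex membrane labels:
#' 0 = lateral, 1 = apical, 2 = basal, 255 = unlabeled.
#' @export
MEMBRANE_LABELS <- c(lateral = 0L, apical = 1L, basal = 2L, unlabeled = 255L)

label_code <- function(label) {
  label <- match.arg(label, names(MEMBRANE_LABELS))
  MEMBRANE_LABELS[[label]]
}

#' Construct a labeled surface mesh
#'
#' A closed triangulated cell surface (positions in micrometers) with a
#' per-vertex membrane label. The volumetric center is computed with the
#' divergence theorem (signed-tetrahedron centroid) when the mesh is closed,
#' and falls back to the vertex centroid (with a warning) when it is open.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions (um).
#' @param triangles integer matrix (m x 3) of 1-based vertex indices,
#'   consistently oriented outward.
#' @param labels integer vector of per-vertex label codes (see
#'   [MEMBRANE_LABELS]), or a character vector of label names; defaults to
#'   all-unlabeled.
#' @param cell_id identifier stored with the mesh.
#' @return object of class `labeled_mesh` with fields `vertices`,
#'   `triangles`, `labels`, `center`, `cell_id`, `closed`.
#' @export
labeled_mesh <- function(vertices, triangles, labels = NULL, cell_id = "cell") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3) stop("mesh has non-triangular faces")
  if (nrow(vertices) < 4 || nrow(triangles) < 4)
    stop("mesh needs at least 4 vertices and 4 triangles")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle references a vertex index out of range")
  if (is.null(labels)) labels <- rep(MEMBRANE_LABELS[["unlabeled"]], nrow(vertices))
  if (is.character(labels)) labels <- MEMBRANE_LABELS[labels]
  labels <- as.integer(unname(labels))
  if (length(labels) != nrow(vertices))
    stop("need one label per vertex")
  if (!all(labels %in% MEMBRANE_LABELS))
    stop("unknown label code; allowed: ", paste(MEMBRANE_LABELS, collapse = ", "))
  closed <- is_closed_mesh(triangles)
  if (closed) {
    center <- volumetric_center(vertices, triangles)
  } else {
    warning("mesh is not closed; using vertex centroid as center")
    center <- colMeans(vertices)
  }
  structure(list(cell_id = cell_id, vertices = vertices, triangles = triangles,
                 labels = labels, center = center, closed = closed),
            class = "labeled_mesh")
}

#' @export
print.labeled_mesh <- function(x, ...) {
  counts <- table(factor(x$labels, levels = MEMBRANE_LABELS,
                         labels = names(MEMBRANE_LABELS)))
  cat(sprintf("labeled_mesh '%s': %d vertices, %d triangles (%s)\n",
              x$cell_id, nrow(x$vertices), nrow(x$triangles),
              if (x$closed) "closed" else "open"))
  cat("  labels:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  cat(sprintf("  center: (%.3f, %.3f, %.3f) um\n",
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

## every undirected edge must be used by exactly two triangles, once in each
## direction (consistent orientation)
is_closed_mesh <- function(triangles) {
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  fwd <- paste(e[, 1], e[, 2])
  rev <- paste(e[, 2], e[, 1])
  all(fwd %in% rev) && !anyDuplicated(fwd)
}

#' Volumetric center of a closed mesh
#'
#' Divergence-theorem centroid: the mesh is decomposed into signed
#' tetrahedra spanned by the origin and each oriented triangle; the centroid
#' is the volume-weighted mean of the tetrahedron centroids.
#'
#' @param vertices n x 3 matrix (um).
#' @param triangles m x 3 integer matrix, outward-oriented.
#' @return length-3 centroid (um).
#' @export
volumetric_center <- function(vertices, triangles) {
  v1 <- vertices[triangles[, 1], , drop = FALSE]
  v2 <- vertices[triangles[, 2], , drop = FALSE]
  v3 <- vertices[triangles[, 3], , drop = FALSE]
  vol <- rowSums(v1 * cross_rows(v2, v3)) / 6    # signed tetra volumes
  V <- sum(vol)
  if (abs(V) < 1e-12) stop("mesh has (near) zero enclosed volume")
  cent <- (v1 + v2 + v3) / 4                     # 4th tetra vertex is the origin
  colSums(cent * vol) / V
}

#' Indices of vertices carrying a given membrane label
#' @param mesh a [labeled_mesh].
#' @param label one of `"apical"`, `"basal"`, `"lateral"`, `"unlabeled"`.
#' @return integer vector of vertex indices.
#' @export
vertices_with_label <- function(mesh, label) {
  which(mesh$labels == label_code(label))
}

#' Apply a rigid transform to a mesh
#' @param mesh a [labeled_mesh].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (um).
#' @return transformed [labeled_mesh].
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, "+")
  m <- mesh
  m$vertices <- v
  m$center <- as.numeric(rotation %*% mesh$center + translation)
  m
}
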