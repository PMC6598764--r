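# Independent oracles and fixture builders used across the suite.

# l'Huilier spherical-excess formula: independent of the
# van Oosterom-Strackee implementation used by the package
lhuilier_solid_angle <- function(a, b, c) {
  arc <- function(u, v) acos(pmin(1, pmax(-1, sum(u * v))))
  A <- arc(b, c); B <- arc(a, c); C <- arc(a, b)
  s <- (A + B + C) / 2
  4 * atan(sqrt(max(0, tan(s / 2) * tan((s - A) / 2) *
                      tan((s - B) / 2) * tan((s - C) / 2))))
}

# uniform random rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# regular tetrahedron with outward-oriented faces
tetra_mesh <- function(labels = c(1L, 1L, 0L, 0L)) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  labeled_mesh(v, f, labels, cell_id = "tetra")
}

# charge set built directly (bypasses meshes) for closed-form field tests
make_charges <- function(positions, charges, vein = NULL) {
  if (is.null(vein)) vein <- ifelse(charges > 0, "CV", "PV")
  structure(list(positions = rbind(positions), charges = charges,
                 vein = factor(vein, levels = c("CV", "PV"))),
            class = "charge_set")
}

# random orthonormal axis frame packaged as polarity_axes (for tests that
# need cell records without building meshes)
random_axes <- function(sigma = c(0.6, -0.45, -0.15)) {
  R <- random_rotation()
  structure(list(axes = rbind(a1 = R[, 1], a2 = R[, 2], a3 = R[, 3]),
                 sigma = sigma, degenerate = c(FALSE, FALSE, FALSE)),
            class = "polarity_axes")
}

# brute-force Eq-style nematic tensor from directions and weights
brute_nematic <- function(dirs, w = rep(1, nrow(dirs))) {
  M <- matrix(0, 3, 3)
  for (i in seq_len(nrow(dirs)))
    M <- M + w[i] * (tcrossprod(dirs[i, ]) - diag(3) / 3)
  1.5 * M / sum(w)
}

# density-grid sidecar location (mirrors the writer's convention)
sidecar_path_for_test <- function(path) paste0(path, ".json")

# sign-free angle between two axes, degrees
axis_angle_deg_for_test <- function(u, v) {
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}
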