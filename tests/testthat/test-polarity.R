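test_that("marker triangles require at least two labeled vertices", {
  m <- tetra_mesh(labels = c(1L, 1L, 0L, 0L))
  sel <- select_marker_triangles(m, "apical")
  hit <- matrix(m$labels[m$triangles] == 1L, ncol = 3)
  expect_setequal(sel, which(rowSums(hit) >= 2))
  ## triangle with a single apical vertex is excluded
  m1 <- tetra_mesh(labels = c(1L, 0L, 0L, 0L))
  expect_length(select_marker_triangles(m1, "apical"), 0)
  ## all-lateral mesh yields the empty set
  m0 <- tetra_mesh(labels = rep(0L, 4))
  expect_length(select_marker_triangles(m0, "apical"), 0)
})

test_that("spherical projection conserves the sphere area", {
  ico <- icosphere(3, radius = 3)     # 1280 faces
  m <- labeled_mesh(ico$vertices, ico$triangles)
  proj <- spherical_projection(m)
  expect_lt(abs(proj$total_area - 4 * pi) / (4 * pi), 0.005)
  expect_equal(proj$n_violations, 0)
  expect_equal(rowSums(proj$directions^2), rep(1, 1280), tolerance = 1e-9)
  ## projected vertex directions are radial unit vectors
  rel <- ico$vertices[1, ] / sqrt(sum(ico$vertices[1, ]^2))
  expect_equal(unname(rel * 3), unname(ico$vertices[1, ]))
})

test_that("solid angles agree with the l'Huilier oracle per triangle", {
  ico <- icosphere(3, radius = 3)
  m <- labeled_mesh(ico$vertices, ico$triangles)
  proj <- spherical_projection(m)
  u <- ico$vertices / 3
  set.seed(1)
  for (i in sample(nrow(ico$triangles), 60)) {
    tri <- ico$triangles[i, ]
    expect_equal(proj$areas[i],
                 lhuilier_solid_angle(u[tri[1], ], u[tri[2], ], u[tri[3], ]),
                 tolerance = 1e-9)
  }
  expect_equal(mean(proj$areas), 4 * pi / 1280, tolerance = 1e-12)
})

test_that("degenerate projection at the center is rejected", {
  m <- tetra_mesh()
  m$center <- m$vertices[1, ]
  expect_error(spherical_projection(m), "degenerate")
})

test_that("nematic tensor reproduces analytic marker distributions", {
  ico <- icosphere(4)   # 5120 faces for quadrature accuracy
  m <- labeled_mesh(ico$vertices, ico$triangles)
  proj <- spherical_projection(m)
  z <- proj$directions[, 3]
  ## two small antipodal caps along z -> diag(-1/2, -1/2, 1)
  caps <- which(abs(z) > cos(6 * pi / 180))
  Ncap <- nematic_tensor(proj, caps)
  expect_equal(unclass(Ncap), diag(c(-0.5, -0.5, 1)), tolerance = 0.02)
  ## uniform marker over the whole sphere -> zero tensor
  Nall <- nematic_tensor(proj, seq_along(proj$areas))
  expect_lt(max(abs(Nall)), 1e-2)
  ## thin equatorial band (85-95 deg): evaluate the tensor on an
  ## azimuthally dense area-weighted direction set and compare against a
  ## brute-force quadrature of the band integral
  th <- rep(seq(85.05, 94.95, by = 0.1) * pi / 180, each = 360)
  ph <- rep(seq(0.5, 359.5, by = 1) * pi / 180, times = 100)
  dirs <- cbind(cos(ph) * sin(th), sin(ph) * sin(th), cos(th))
  band_proj <- structure(list(areas = sin(th), directions = dirs,
                              marker_mask = seq_along(th)),
                         class = "projected_triangles")
  Nband <- nematic_tensor(band_proj)
  thq <- seq(85, 95, length.out = 4001) * pi / 180
  wq <- sin(thq)
  Ezz <- sum(cos(thq)^2 * wq) / sum(wq)
  oracle <- diag(c((1 - Ezz) * 1.5 / 2 - 0.5, (1 - Ezz) * 1.5 / 2 - 0.5,
                   1.5 * Ezz - 0.5))
  expect_equal(unclass(Nband), oracle, tolerance = 1e-4)
  expect_equal(diag(unclass(Nband)), c(0.25, 0.25, -0.5), tolerance = 0.02)
  expect_error(nematic_tensor(proj, integer(0)), "marker")
})

test_that("eigen-axes follow the sigma2 <= sigma3 <= sigma1 convention", {
  p <- polarity_axes(structure(diag(c(-0.5, -0.5, 1)),
                               class = c("nematic_tensor", "matrix")))
  expect_equal(p$sigma[1], 1)
  expect_equal(abs(p$axes[1, ]), c(0, 0, 1))
  expect_true(p$degenerate[2])     # ring axis degenerate for pure bipolar
  expect_false(p$degenerate[1])
  p2 <- polarity_axes(structure(diag(c(0.25, 0.25, -0.5)),
                                class = c("nematic_tensor", "matrix")))
  expect_equal(p2$sigma[2], -0.5)
  expect_equal(abs(p2$axes[2, ]), c(0, 0, 1))
  expect_true(p2$degenerate[1])    # bipolar axis degenerate for pure ring
  expect_false(p2$degenerate[2])
  ## random symmetric traceless tensors: spectral sanity
  set.seed(2)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3); A <- (A + t(A)) / 2; A <- A - diag(3) * sum(diag(A)) / 3
    p3 <- polarity_axes(A)
    expect_equal(sum(p3$sigma), 0, tolerance = 1e-10)
    expect_equal(p3$axes %*% t(p3$axes), diag(3), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(p3$sigma[2] <= p3$sigma[3] && p3$sigma[3] <= p3$sigma[1])
  }
})

test_that("the polarity tensor is rotation-equivariant", {
  set.seed(3)
  mesh <- generate_cell_mesh("mixed", axis = c(0, 0, 1), seed = 9)
  N <- unclass(nematic_tensor(spherical_projection(mesh)))
  for (i in 1:5) {
    R <- random_rotation()
    mr <- transform_mesh(mesh, R, runif(3, -50, 50))
    Nr <- unclass(nematic_tensor(spherical_projection(mr)))
    expect_equal(Nr, R %*% N %*% t(R), tolerance = 1e-8)
  }
})

test_that("eigenvalue weights stay in the nematic range", {
  set.seed(4)
  for (i in 1:15) {
    mesh <- generate_cell_mesh(sample(c("pure_bipolar", "pure_ring", "mixed"), 1),
                               axis = runif_sphere(1)[1, ], seed = 50 + i)
    p <- cell_polarity(mesh)
    expect_gte(p$sigma[1], 0)
    expect_lte(p$sigma[1], 1 + 1e-9)
    expect_gte(p$sigma[2], -0.5 - 1e-9)
    expect_lte(p$sigma[2], 0)
  }
})

test_that("bipolar axes are recovered from noisy caps", {
  set.seed(6)
  errs <- vapply(1:200, function(i) {
    ax <- runif_sphere(1)[1, ]
    mesh <- generate_cell_mesh("pure_bipolar", axis = ax, noise_kappa = 20,
                               seed = 2000 + i)
    p <- cell_polarity(mesh)
    acos(min(1, abs(sum(p$axes[1, ] * ax)))) * 180 / pi
  }, 0)
  expect_lt(median(errs), 2)
})

test_that("pure generator presets land on the extreme weight lines", {
  set.seed(7)
  bi <- vapply(1:10, function(i) {
    cell_polarity(generate_cell_mesh("pure_bipolar", seed = i))$sigma[1:2]
  }, numeric(2))
  ## pure bipolar: sigma2 = -sigma1/2 (golden line)
  expect_lt(max(abs(bi[2, ] + bi[1, ] / 2)), 0.02)
  ring <- vapply(1:10, function(i) {
    cell_polarity(generate_cell_mesh("pure_ring", seed = 100 + i))$sigma[2]
  }, 0)
  expect_lt(max(abs(ring + 0.5)), 0.02)
})

test_that("complementary basal patterns repel apical axes", {
  set.seed(8)
  cells <- lapply(1:25, function(i) {
    ax <- runif_sphere(1)[1, ]
    mesh <- generate_cell_mesh("mixed", axis = ax, seed = 300 + i)
    proj <- spherical_projection(mesh)
    rec <- cell_record(i, c(0, 0, 0))
    rec$apical <- polarity_axes(nematic_tensor(proj))
    rec$basal <- polarity_axes(nematic_tensor(
      proj, select_marker_triangles(mesh, "basal")))
    rec
  })
  tab <- axis_cross_correlation(cells)
  S <- setNames(tab$S, tab$pair)
  expect_lt(S[["a1-b1"]], 0)
  expect_lt(S[["a2-b2"]], 0)
  expect_gt(S[["a1-b2"]], 0)
  expect_gt(S[["a2-b1"]], 0)
})

test_that("independent isotropic apical and basal axes are uncorrelated", {
  set.seed(9)
  cells <- lapply(1:10000, function(i) {
    rec <- cell_record(i, c(0, 0, 0))
    rec$apical <- random_axes()
    rec$basal <- random_axes()
    rec
  })
  tab <- axis_cross_correlation(cells)
  expect_true(all(abs(tab$S) < 0.02))
})

test_that("Mollweide maps the frame anchor points correctly", {
  xy <- mollweide_xy(0, 0)
  expect_equal(unname(xy[1, ]), c(0, 0))
  expect_equal(unname(mollweide_xy(0, pi / 2)[1, ]), c(0, sqrt(2)))
  expect_equal(unname(mollweide_xy(pi, 0)[1, ]), c(2 * sqrt(2), 0))
})

test_that("the Mollweide projection is equal-area", {
  set.seed(10)
  u <- runif_sphere(100000)
  lon <- atan2(u[, 2], u[, 1])
  lat <- asin(u[, 3])
  xy <- mollweide_xy(lon, lat)
  ## all points inside the bounding ellipse of area 4*pi
  r2 <- (xy[, 1] / (2 * sqrt(2)))^2 + (xy[, 2] / sqrt(2))^2
  expect_true(all(r2 <= 1 + 1e-9))
  ## uniform density: the half-area concentric ellipse holds half the mass
  expect_equal(mean(r2 <= 0.5), 0.5, tolerance = 0.01)
  ## and the left half-plane holds half the mass
  expect_equal(mean(xy[, 1] < 0), 0.5, tolerance = 0.01)
})

test_that("per-cell Mollweide coordinates center the apical bipolar axis", {
  mesh <- generate_cell_mesh("mixed", axis = c(0, 0, 1), ring_axis = c(1, 0, 0),
                             noise_kappa = Inf, seed = 1)
  proj <- spherical_projection(mesh)
  ap <- polarity_axes(nematic_tensor(proj))
  ba <- polarity_axes(nematic_tensor(proj, select_marker_triangles(mesh, "basal")))
  mw <- mollweide_coordinates(mesh, ap, ba)
  expect_true(all(abs(mw$x) <= 2 * sqrt(2) + 1e-9))
  ## one apical cap sits at the map center: points exist near (0, 0)
  expect_true(any(abs(mw$lon) < 0.3 & abs(mw$lat) < 0.3))
  ## parallel frame axes are rejected
  expect_error(mollweide_coordinates(mesh, ap, ap), "degenera|parallel")
})
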