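test_that("cell meshes are deterministic given a seed and star-convex", {
  m1 <- generate_cell_mesh("mixed", seed = 31)
  m2 <- generate_cell_mesh("mixed", seed = 31)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$labels, m2$labels)
  set.seed(32)
  for (i in 1:10) {
    m <- generate_cell_mesh(sample(c("pure_bipolar", "pure_ring", "mixed"), 1),
                            axis = runif_sphere(1)[1, ], seed = 600 + i)
    proj <- spherical_projection(m)
    expect_equal(proj$n_violations, 0)
    expect_lt(abs(proj$total_area - 4 * pi) / (4 * pi), 0.005)
  }
  expect_error(generate_cell_mesh("mixed", mesh_subdivisions = 0), ">= 1")
})

test_that("ideal presets reach the analytic polarity extremes", {
  bi <- cell_polarity(generate_cell_mesh("pure_bipolar", noise_kappa = Inf,
                                         seed = 1))
  expect_equal(bi$sigma[1], 1, tolerance = 0.03)
  expect_lt(axis_angle_deg_for_test(bi$axes[1, ], c(0, 0, 1)), 2)
  ring <- cell_polarity(generate_cell_mesh("pure_ring", noise_kappa = Inf,
                                           seed = 1))
  expect_equal(ring$sigma[2], -0.5, tolerance = 0.03)
})

test_that("measured axes close the loop against stored ground truth", {
  ## bipolar pattern: the recovery protocol the axis estimator is rated on
  lob <- generate_lobule(lobule_config(n_cells = 60, noise_kappa = 20,
                                       apical_pattern = "pure_bipolar",
                                       seed = 33))
  errs <- vapply(seq_along(lob$cells), function(i) {
    p <- cell_polarity(lob$meshes[[i]])
    acos(min(1, abs(sum(p$axes[1, ] * lob$cells[[i]]$true_a1)))) * 180 / pi
  }, 0)
  expect_lt(median(errs), 3)
  ## mixed pattern: the belt's boundary wobble deflects the bipolar axis
  ## more, but both true axes remain clearly recovered
  lobm <- generate_lobule(lobule_config(n_cells = 60, noise_kappa = 20,
                                        seed = 38))
  errm <- t(vapply(seq_along(lobm$cells), function(i) {
    p <- cell_polarity(lobm$meshes[[i]])
    c(acos(min(1, abs(sum(p$axes[1, ] * lobm$cells[[i]]$true_a1)))),
      acos(min(1, abs(sum(p$axes[2, ] * lobm$cells[[i]]$true_a2))))) * 180 / pi
  }, numeric(2)))
  expect_lt(median(errm[, 1]), 10)
  expect_lt(median(errm[, 2]), 10)
})

test_that("lobule alignment follows the Watson concentration", {
  ## perfect alignment at very large concentration
  lob_inf <- generate_lobule(lobule_config(n_cells = 60, kappa_align = 1e7,
                                           seed = 34), make_meshes = FALSE)
  A1 <- t(vapply(lob_inf$cells, function(cl) cl$true_a1, numeric(3)))
  expect_equal(alignment_parameter(A1, lob_inf$J), 1, tolerance = 0.02)
  ## isotropy at zero concentration
  lob0 <- generate_lobule(lobule_config(n_cells = 500, kappa_align = 0,
                                        lobule_extent = c(420, 420, 100),
                                        seed = 35), make_meshes = FALSE)
  A0 <- t(vapply(lob0$cells, function(cl) cl$true_a1, numeric(3)))
  expect_lt(abs(alignment_parameter(A0, lob0$J)), 0.03)
  ## intermediate concentration matches the quadrature oracle
  lob5 <- generate_lobule(lobule_config(n_cells = 500, kappa_align = 5,
                                        lobule_extent = c(420, 420, 100),
                                        seed = 36), make_meshes = FALSE)
  A5 <- t(vapply(lob5$cells, function(cl) cl$true_a1, numeric(3)))
  expect_equal(alignment_parameter(A5, lob5$J), watson_order_parameter(5),
               tolerance = 0.03)
})

test_that("infeasible packings are rejected", {
  expect_error(generate_lobule(lobule_config(n_cells = 2000,
                                             lobule_extent = c(80, 80, 40)),
                               make_meshes = FALSE),
               "infeasible")
})

test_that("layered grids are complementary, periodic and reproducible", {
  cfg <- lobule_config(layer_jitter = 0, voxel_size = 0.6)
  g <- generate_layered_grid(cfg, extent = c(96, 48, 3), seed = 37)
  expect_true(all(g$hepatocyte$values + g$sinusoid$values == 1))
  ## zero jitter: slabs repeat exactly every layer_spacing along y
  slab <- g$sinusoid$values[1, , 1]
  shift_vox <- cfg$layer_spacing / cfg$voxel_size
  expect_equal(slab[seq_len(length(slab) - shift_vox)],
               slab[(shift_vox + 1):length(slab)])
  ## bc bands live inside hepatocyte slabs
  expect_true(all(g$hepatocyte$values[g$bc$values > 0] == 1))
  g2 <- generate_layered_grid(cfg, extent = c(96, 48, 3), seed = 37)
  expect_identical(g2$sinusoid$values, g$sinusoid$values)
  expect_warning(generate_layered_grid(lobule_config(layer_jitter = 0.6),
                                       extent = c(30, 30, 3)),
                 "merge")
})

test_that("reduced coupling preserves per-cell polarity distributions", {
  ## knockdown-like preset: same apical patterns, weaker tissue order
  n_rep <- 3
  ord_sig <- kd_sig <- NULL
  ord_S <- kd_S <- numeric(n_rep)
  for (r in 1:n_rep) {
    ordc <- lobule_config(n_cells = 50, seed = 700 + r)
    kdc <- disordered_config(lobule_config(n_cells = 50, seed = 800 + r))
    lo <- generate_lobule(ordc)
    lk <- generate_lobule(kdc)
    po <- lapply(lo$meshes, cell_polarity)
    pk <- lapply(lk$meshes, cell_polarity)
    ord_sig <- rbind(ord_sig, t(vapply(po, function(p) p$sigma[1:2], numeric(2))))
    kd_sig <- rbind(kd_sig, t(vapply(pk, function(p) p$sigma[1:2], numeric(2))))
    get_S <- function(lob, pol) {
      A <- t(vapply(pol, function(p) p$axes[1, ], numeric(3)))
      alignment_parameter(A, lob$J)
    }
    ord_S[r] <- get_S(lo, po)
    kd_S[r] <- get_S(lk, pk)
  }
  expect_gt(mean(ord_S), mean(kd_S) + 0.2)
  expect_gt(stats::ks.test(ord_sig[, 1], kd_sig[, 1])$p.value, 0.1)
  expect_gt(stats::ks.test(ord_sig[, 2], kd_sig[, 2])$p.value, 0.1)
})
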