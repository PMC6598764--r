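test_that("density projection averages along the chosen axis", {
  g <- density_grid(array(3, c(4, 5, 6)), 0.3)
  img <- project_density(g, "z")
  expect_true(all(img$values == 3))
  expect_equal(dim(img$values), c(4, 5))
  expect_equal(img$pixel_size, 0.3)
  ## single nonzero voxel dilutes by the depth
  vals <- array(0, c(4, 5, 10)); vals[2, 3, 7] <- 1
  img2 <- project_density(density_grid(vals, 0.3), "z")
  expect_equal(img2$values[2, 3], 1 / 10)
  expect_equal(sum(img2$values), 1 / 10)
  ## mass conservation
  set.seed(23)
  vals3 <- array(runif(4 * 5 * 6), c(4, 5, 6))
  img3 <- project_density(density_grid(vals3, 0.3), "z")
  expect_equal(sum(img3$values) * 6, sum(vals3), tolerance = 1e-12)
})

test_that("the printed-prefactor normalization gives 1/2 at zero lag", {
  set.seed(24)
  A <- matrix(runif(400), 20, 20)
  Si <- density_image(A, 0.3)
  C <- normalized_crosscorr(Si, Si)
  expect_equal(C$values[match(0, C$k_lags), match(0, C$l_lags)], 0.5,
               tolerance = 1e-12)
  ## conventional overlap normalization gives 1 at zero lag
  Co <- normalized_crosscorr(Si, Si, normalization = "overlap")
  expect_equal(Co$values[match(0, Co$k_lags), match(0, Co$l_lags)], 1,
               tolerance = 1e-12)
  ## independent white noise decorrelates
  set.seed(25)
  B <- matrix(runif(10000), 100, 100)
  D <- matrix(runif(10000), 100, 100)
  Cw <- normalized_crosscorr(density_image(B, 0.3), density_image(D, 0.3))
  expect_lt(abs(Cw$values[match(0, Cw$k_lags), match(0, Cw$l_lags)]), 0.05)
  expect_error(normalized_crosscorr(Si, density_image(matrix(1, 20, 20), 0.3)),
               "flat")
})

test_that("cross-correlation matches the direct-sum oracle on 32x32 images", {
  set.seed(26)
  A <- matrix(runif(32 * 32), 32, 32)
  B <- matrix(runif(32 * 32), 32, 32)
  C <- normalized_crosscorr(density_image(A, 0.3), density_image(B, 0.3))
  muA <- mean(A); muB <- mean(B)
  sdA <- sqrt(mean((A - muA)^2)); sdB <- sqrt(mean((B - muB)^2))
  Bc <- B - muB
  direct <- function(k, l) {
    s <- 0
    for (n in 1:32) for (m in 1:32) {
      nn <- n + k; mm <- m + l
      if (nn >= 1 && nn <= 32 && mm >= 1 && mm <= 32)
        s <- s + (A[n, m] - muA) * Bc[nn, mm]
    }
    s / ((2 * 32 * 32) * sdA * sdB)
  }
  for (kl in list(c(0, 0), c(5, 3), c(-7, 12), c(31, -31), c(-16, 0))) {
    expect_equal(C$values[match(kl[1], C$k_lags), match(kl[2], C$l_lags)],
                 direct(kl[1], kl[2]), tolerance = 1e-10)
  }
  ## a shifted copy peaks at its shift
  k0 <- 6; l0 <- -4
  Bs <- matrix(0, 32, 32)
  Bs[pmax(1, 1 + k0):pmin(32, 32 + k0), pmax(1, 1 + l0):pmin(32, 32 + l0)] <-
    A[pmax(1, 1 - k0):pmin(32, 32 - k0), pmax(1, 1 - l0):pmin(32, 32 - l0)]
  Cs <- normalized_crosscorr(density_image(A, 0.3), density_image(Bs, 0.3))
  idx <- which(Cs$values == max(Cs$values), arr.ind = TRUE)
  expect_equal(Cs$k_lags[idx[1]], k0)
  expect_equal(Cs$l_lags[idx[2]], l0)
})

test_that("swapping the images mirrors the correlation array", {
  set.seed(27)
  A <- matrix(runif(24 * 18), 24, 18)
  B <- matrix(runif(24 * 18), 24, 18)
  Cab <- normalized_crosscorr(density_image(A, 0.3), density_image(B, 0.3))
  Cba <- normalized_crosscorr(density_image(B, 0.3), density_image(A, 0.3))
  mirrored <- Cba$values[rev(seq_along(Cba$k_lags)),
                         rev(seq_along(Cba$l_lags))]
  expect_equal(Cab$values, mirrored, tolerance = 1e-10)
})

test_that("line profiles implement the binned mean projection", {
  set.seed(28)
  C <- structure(list(values = matrix(runif(21 * 15), 21, 15),
                      k_lags = -10:10, l_lags = -7:7, pixel_size = 0.3),
                 class = "correlation_map")
  p <- line_profile(C, c(1, 0), bin_size = 0.3)
  ## direction (1, 0): bins collapse to row means at each k lag
  expect_equal(p$value, unname(rowMeans(C$values)), tolerance = 1e-12)
  expect_equal(p$lag, C$k_lags * 0.3)
  ## constant array gives a constant profile
  C$values[] <- 0.7
  pc <- line_profile(C, c(0, 1), bin_size = 0.3)
  expect_true(all(abs(pc$value - 0.7) < 1e-12))
  ## separable array: profile proportional to binned f times mean of g
  f <- sin(-10:10); g <- seq(0.5, 1.5, length.out = 15)
  C$values <- outer(f, g)
  ps <- line_profile(C, c(1, 0), bin_size = 0.3)
  expect_equal(ps$value, f * mean(g), tolerance = 1e-12)
  expect_error(line_profile(C, c(2, 0)), "unit")
})

test_that("a cosine profile yields its construction period", {
  lag <- seq(-60, 60, by = 1.5)
  prof <- structure(data.frame(lag = lag, value = cos(2 * pi * lag / 24)),
                    bin_size = 1.5,
                    class = c("correlation_profile", "data.frame"))
  res <- estimate_period(prof)
  expect_equal(res$period, 24, tolerance = 0.75)
  ## pure noise has no admissible peak structure above its null band
  set.seed(29)
  noise <- array(runif(80 * 80 * 2), c(80, 80, 2))
  gn1 <- density_grid(noise, 0.3)
  gn2 <- density_grid(array(runif(80 * 80 * 2), c(80, 80, 2)), 0.3)
  resn <- layered_order_analysis(gn1, gn2, direction = c(0, 1), n_null = 60)
  expect_false(isTRUE(resn$period$significant) && !is.na(resn$period$period) &&
                 resn$period$peak_value > 2 * resn$period$null_threshold)
})

test_that("layered grids reveal the construction period and its absence in the control", {
  cfg <- lobule_config(voxel_size = 0.6)
  g <- generate_layered_grid(cfg, extent = c(150, 150, 3), seed = 5)
  res <- layered_order_analysis(g$sinusoid, g$hepatocyte,
                                direction = g$layer_normal, n_null = 100)
  expect_true(res$period$significant)
  expect_equal(res$period$period, 24, tolerance = 1.5)
  expect_equal(res$period$extremum, "minimum")
  ## control direction along the CV-PV axis: no periodicity
  ctrl <- layered_order_analysis(g$sinusoid, g$hepatocyte,
                                 direction = c(1, 0), n_null = 100)
  expect_true(is.na(ctrl$period$period))
  ## hepatocyte vs bile canaliculi repeats as a maximum
  hb <- layered_order_analysis(g$hepatocyte, g$bc,
                               direction = g$layer_normal, n_null = 100)
  expect_equal(hb$period$extremum, "maximum")
  expect_equal(hb$period$period, 24, tolerance = 3)
})

test_that("the period estimate is invariant under in-plane rotation", {
  cfg <- lobule_config(voxel_size = 0.6)
  ang <- 30 * pi / 180
  dirs <- rbind(c(0, 1), c(sin(ang), cos(ang)))
  periods <- apply(dirs, 1, function(d) {
    g <- generate_layered_grid(cfg, extent = c(120, 120, 3),
                               layer_normal = d, seed = 6)
    layered_order_analysis(g$sinusoid, g$hepatocyte, direction = d,
                           n_null = 60)$period$period
  })
  expect_equal(periods[1], periods[2], tolerance = 1.5)
})
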