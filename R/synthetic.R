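## Synthetic-lobule generator with known ground truth. Emulates the
## statistical structure the analysis assumes: star-convex hepatocyte
## meshes with apical patch patterns spanning bipolar-to-ring morphologies,
## cell centers packed between two parallel vein cylinders, polarity axes
## Watson-dispersed about the local reference field J, a sinusoid skeleton
## co-aligned with J, and alternating hepatocyte/sinusoid layered density
## grids with controllable spacing and jitter.

#' Synthetic lobule configuration
#'
#' Defaults describe a confluent mid-lobule block: hepatocyte diameter
#' 20 um (cell_radius 10), sinusoid tube diameter 4 um, hence a layer
#' spacing of 24 um; apical bipolar axes Watson-concentrated about J with
#' `kappa_align = 5` and sinusoid segment orientations with
#' `sinusoid_kappa = 10`. The central and portal veins are parallel
#' cylinders along z at opposite x ends, so J runs along x between them and
#' layers stack along y.
#'
#' @param ... overrides of the default fields: `cv_radius`, `pv_radius`
#'   (um), `lobule_extent` (length-3, um), `n_cells`, `cell_radius` (um),
#'   `apical_pattern` (`"pure_bipolar"`, `"pure_ring"`, `"mixed"`),
#'   `mix_weight`, `kappa_align`, `ring_coupling`, `ring_jitter_sd`
#'   (radians), `basal_complement`, `sinusoid_kappa`, `sinusoid_width`
#'   (um), `layer_spacing` (um), `layer_jitter` (fraction of the spacing),
#'   `noise_kappa` (patch-boundary sharpness), `mesh_subdivisions`,
#'   `voxel_size` (um), `seed`.
#' @return list of class `lobule_config`.
#' @export
lobule_config <- function(...) {
  cfg <- list(
    cv_radius = 20, pv_radius = 15,
    lobule_extent = c(250, 250, 60),
    n_cells = 150, cell_radius = 10,
    apical_pattern = "mixed", mix_weight = 0.5,
    kappa_align = 5, ring_coupling = TRUE, ring_jitter_sd = 0.35,
    basal_complement = TRUE,
    sinusoid_kappa = 10, sinusoid_width = 4,
    layer_spacing = 24, layer_jitter = 0.1,
    noise_kappa = 20, mesh_subdivisions = 3,
    voxel_size = 0.3,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$cv_radius > 0, cfg$pv_radius > 0, cfg$cell_radius > 0,
            all(cfg$lobule_extent > 0), cfg$kappa_align >= 0,
            cfg$sinusoid_kappa >= 0, cfg$layer_spacing > 0,
            cfg$layer_jitter >= 0, cfg$layer_jitter <= 1)
  structure(cfg, class = "lobule_config")
}

#' Disordered ("knockdown-like") variant of a configuration
#'
#' Reduces the orientational coupling of cell polarity and sinusoid
#' segments to the reference field while leaving the per-cell apical
#' patterns untouched, mirroring a perturbation that destroys tissue-level
#' order but not cell-intrinsic polarity.
#'
#' @param config a [lobule_config].
#' @param kappa_align,sinusoid_kappa reduced concentrations; defaults 0.3
#'   and 0.5.
#' @return a `lobule_config`.
#' @export
disordered_config <- function(config = lobule_config(), kappa_align = 0.3,
                              sinusoid_kappa = 0.5) {
  config$kappa_align <- kappa_align
  config$sinusoid_kappa <- sinusoid_kappa
  config$ring_coupling <- FALSE
  config
}

#' Read / write a lobule configuration as YAML
#' @param path file path.
#' @return [lobule_config] for the reader; `path` invisibly for the writer.
#' @export
read_lobule_config <- function(path) {
  do.call(lobule_config, yaml::read_yaml(path))
}

#' @rdname read_lobule_config
#' @param config a [lobule_config].
#' @export
write_lobule_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Generate one labeled hepatocyte mesh
#'
#' An icosphere-based closed star-convex mesh with gentle random radial
#' modulation, carrying an apical patch pattern:
#' * `pure_bipolar`: two antipodal caps of half-angle `cap_angle` about
#'   `axis`;
#' * `pure_ring`: an equatorial band of half-width `band_angle` normal to
#'   `axis`;
#' * `mixed`: caps about `axis` plus a band normal to `ring_axis`
#'   (perpendicular to `axis`), band half-width `24 * mix_weight` degrees,
#'   giving an apical surface fraction in the 10--25% range typical of
#'   hepatocytes so the complementary basal pattern also carries
#'   well-defined axes.
#'
#' Patch boundaries are perturbed by a smooth random azimuthal wobble
#' (low-order Fourier modes) of total angular amplitude `1/noise_kappa`
#' radians, so patches stay contiguous, as membrane domains are; larger
#' `noise_kappa` gives more regular patches and `Inf` gives ideal ones.
#' With `basal_complement` the complement of the apical domain is labeled
#' basal except for a lateral ring of `lateral_margin` degrees around the
#' apical patches; otherwise all non-apical vertices stay lateral.
#'
#' @param pattern `"pure_bipolar"`, `"pure_ring"` or `"mixed"`.
#' @param axis primary (bipolar) pattern axis; unit length-3.
#' @param ring_axis ring-normal axis for `mixed` (defaults to an arbitrary
#'   perpendicular of `axis`).
#' @param noise_kappa patch-boundary sharpness; default 20.
#' @param mesh_subdivisions icosphere subdivisions (>= 1); default 3
#'   (1280 triangles).
#' @param radius mean cell radius (um); default 10.
#' @param cap_angle bipolar cap half-angle (degrees); default 10.
#' @param band_angle ring band half-width (degrees); default 5.
#' @param mix_weight ring weight for `mixed` in (0, 1]; default 0.5.
#' @param bump_amplitude relative radial modulation amplitude; default 0.08.
#' @param basal_complement label the complement of the apical domain basal;
#'   default TRUE.
#' @param lateral_margin angular width (degrees) of the lateral ring kept
#'   between the apical and basal domains; default 15.
#' @param cell_id identifier.
#' @param seed optional integer; same seed, same mesh.
#' @return a [labeled_mesh].
#' @export
generate_cell_mesh <- function(pattern = c("pure_bipolar", "pure_ring", "mixed"),
                               axis = c(0, 0, 1), ring_axis = NULL,
                               noise_kappa = 20, mesh_subdivisions = 3,
                               radius = 10, cap_angle = 10, band_angle = 5,
                               mix_weight = 0.5, bump_amplitude = 0.08,
                               basal_complement = TRUE, lateral_margin = 15,
                               cell_id = "cell", seed = NULL) {
  pattern <- match.arg(pattern)
  if (mesh_subdivisions < 1) stop("mesh_subdivisions must be >= 1")
  axis <- as.numeric(axis) / sqrt(sum(axis^2))
  if (is.null(ring_axis)) {
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ring_axis <- as.numeric(cross_rows(axis, ref))
  }
  ring_axis <- as.numeric(ring_axis) / sqrt(sum(ring_axis^2))
  with_local_seed(seed, {
    base <- icosphere(mesh_subdivisions, radius = 1)
    u <- base$vertices
    ## smooth random radial modulation from a few quadratic lobes,
    ## small enough to preserve star-convexity
    lobes <- runif_sphere(4)
    coef <- stats::runif(4, -1, 1)
    bump <- as.numeric((u %*% t(lobes))^2 %*% coef)
    bump <- bump / max(1, max(abs(bump)))
    r <- radius * (1 + bump_amplitude * bump)
    vertices <- u * r

    ## smooth azimuthal boundary wobble: 3 Fourier modes with total angular
    ## standard deviation 1/noise_kappa radians
    wobble_fn <- function() {
      if (!is.finite(noise_kappa)) return(function(phi) 0)
      a <- stats::rnorm(3, 0, 1 / (noise_kappa * sqrt(6)))
      b <- stats::rnorm(3, 0, 1 / (noise_kappa * sqrt(6)))
      function(phi) {
        kphi <- outer(1:3, phi)
        as.numeric(colSums(a * cos(kphi) + b * sin(kphi)))
      }
    }
    azimuth <- function(a) {
      ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- as.numeric(cross_rows(a, ref)); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- as.numeric(cross_rows(a, e1))
      atan2(as.numeric(u %*% e2), as.numeric(u %*% e1))
    }
    caps_about <- function(a, half_angle) {
      t <- as.numeric(u %*% a)
      phi <- azimuth(a)
      theta_pole <- acos(pmin(1, abs(t)))
      w_top <- wobble_fn(); w_bot <- wobble_fn()
      bound <- half_angle + ifelse(t >= 0, w_top(phi), w_bot(phi))
      theta_pole <= bound
    }
    band_about <- function(a, half_width) {
      t <- as.numeric(u %*% a)
      phi <- azimuth(a)
      theta <- acos(pmin(1, pmax(-1, t)))        # polar angle from the normal
      w_shift <- wobble_fn(); w_edge <- wobble_fn()
      abs(theta - pi / 2 - w_shift(phi)) <= half_width + w_edge(phi)
    }
    cap_rad <- cap_angle * pi / 180
    band_rad <- band_angle * pi / 180
    apical <- switch(pattern,
      pure_bipolar = caps_about(axis, cap_rad),
      pure_ring = band_about(axis, band_rad),
      ## mixed: enlarged caps so the bipolar weight stays well separated
      ## from the middle eigenvalue even with a dominant ring band (the
      ## caps sit on the ring, as the bipolar poles lie in the ring plane)
      mixed = caps_about(axis, 2.5 * cap_rad) |
        band_about(ring_axis, pmax(0.02, mix_weight) * 24 * pi / 180))
    labels <- rep(MEMBRANE_LABELS[["lateral"]], nrow(u))
    if (basal_complement && any(apical) && !all(apical)) {
      ## basal on the complement, separated from the apical domain by a
      ## lateral margin ring, as in hepatocytes
      cosang <- u[!apical, , drop = FALSE] %*% t(u[apical, , drop = FALSE])
      min_angle <- acos(pmin(1, apply(cosang, 1, max)))
      basal <- which(!apical)[min_angle > lateral_margin * pi / 180]
      labels[basal] <- MEMBRANE_LABELS[["basal"]]
    }
    labels[apical] <- MEMBRANE_LABELS[["apical"]]
    labeled_mesh(vertices, base$triangles, labels, cell_id = cell_id)
  })
}

## dart-throwing Poisson-disk sampling in a box with exclusion balls
poisson_disk_sample <- function(n, lower, upper, min_dist,
                                exclude = NULL, max_tries = 100000) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0
  tries <- 0
  while (got < n && tries < max_tries) {
    tries <- tries + 1
    p <- stats::runif(3, lower, upper)
    if (!is.null(exclude) && any(vapply(exclude, function(e)
      sum((p[1:2] - e$center_xy)^2) < e$radius^2, TRUE))) next
    if (got > 0) {
      d2 <- rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, p)^2)
      if (min(d2) < min_dist^2) next
    }
    got <- got + 1
    pts[got, ] <- p
  }
  if (got < n)
    stop("infeasible packing: placed ", got, " of ", n,
         " cells after ", max_tries, " tries")
  pts
}

## open triangulated cylinder along z; axial sampling kept comparable to
## the azimuthal charge spacing so the discretized surface charge density
## stays smooth near the surface
cylinder_mesh <- function(center_xy, radius, z_range, n_seg = 24,
                          n_z = max(6L, ceiling(diff(z_range) / 8))) {
  theta <- seq(0, 2 * pi, length.out = n_seg + 1)[-(n_seg + 1)]
  zs <- seq(z_range[1], z_range[2], length.out = n_z + 1)
  verts <- do.call(rbind, lapply(zs, function(z)
    cbind(center_xy[1] + radius * cos(theta),
          center_xy[2] + radius * sin(theta), z)))
  tri <- list()
  for (iz in seq_len(n_z)) {
    base0 <- (iz - 1) * n_seg
    base1 <- iz * n_seg
    for (it in seq_len(n_seg)) {
      jt <- it %% n_seg + 1
      tri[[length(tri) + 1]] <- c(base0 + it, base0 + jt, base1 + it)
      tri[[length(tri) + 1]] <- c(base0 + jt, base1 + jt, base1 + it)
    }
  }
  list(vertices = verts, triangles = do.call(rbind, tri))
}

#' Generate a synthetic lobule
#'
#' Builds central- and portal-vein cylinders at opposite x ends of the
#' lobule box, Poisson-disk samples cell centers between them, draws each
#' cell's true bipolar axis from a Watson distribution about the local
#' reference direction J (concentration `kappa_align`), places the true
#' ring axis in the plane normal to the bipolar axis (biased toward the
#' in-plane component of J when `ring_coupling` is on, uniform in the plane
#' otherwise), grows a sinusoid skeleton whose segment orientations are
#' Watson-distributed about J, and (optionally) generates one labeled mesh
#' per cell realizing the configured apical pattern about the true axes.
#'
#' @param config a [lobule_config].
#' @param make_meshes generate per-cell labeled meshes (default TRUE).
#' @return list of class `synthetic_lobule` with `cells` (list of
#'   [cell_record] with ground-truth axes in `$true_a1`, `$true_a2`),
#'   `meshes` (list of [labeled_mesh] or `NULL`), `cv_mesh`, `pv_mesh`,
#'   `charges`, `skeleton` ([network_skeleton]), `J` (per-cell reference
#'   direction) and `config`.
#' @export
generate_lobule <- function(config = lobule_config(), make_meshes = TRUE) {
  stopifnot(inherits(config, "lobule_config"))
  with_local_seed(config$seed, {
    L <- config$lobule_extent
    margin <- config$cell_radius
    cv_xy <- c(config$cv_radius, L[2] / 2)
    pv_xy <- c(L[1] - config$pv_radius, L[2] / 2)
    cv <- cylinder_mesh(cv_xy, config$cv_radius, c(-L[3], 2 * L[3]))
    pv <- cylinder_mesh(pv_xy, config$pv_radius, c(-L[3], 2 * L[3]))
    charges <- build_charges(cv, pv)

    excl <- list(list(center_xy = cv_xy, radius = config$cv_radius + margin),
                 list(center_xy = pv_xy, radius = config$pv_radius + margin))
    pos <- poisson_disk_sample(config$n_cells,
                               lower = rep(margin, 3),
                               upper = L - margin,
                               min_dist = 0.9 * 2 * config$cell_radius,
                               exclude = excl)
    Jres <- reference_direction(pos, charges, exclusion_radius = 0.5)
    J <- Jres$J

    cells <- vector("list", config$n_cells)
    meshes <- if (make_meshes) vector("list", config$n_cells) else NULL
    for (i in seq_len(config$n_cells)) {
      j <- J[i, ]
      a1 <- if (is.finite(config$kappa_align) && config$kappa_align < 1e6) {
        as.numeric(rwatson(1, j, config$kappa_align))
      } else j
      ## true ring axis in the plane normal to a1
      ref <- if (abs(a1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- as.numeric(cross_rows(a1, ref)); e1 <- e1 / sqrt(sum(e1^2))
      e2 <- as.numeric(cross_rows(a1, e1))
      if (isTRUE(config$ring_coupling)) {
        jp <- j - sum(j * a1) * a1        # in-plane component of J
        npj <- sqrt(sum(jp^2))
        base_phi <- if (npj > 1e-9) atan2(sum(jp * e2), sum(jp * e1))
                    else stats::runif(1, 0, 2 * pi)
        phi <- base_phi + stats::rnorm(1, 0, config$ring_jitter_sd)
      } else {
        phi <- stats::runif(1, 0, 2 * pi)
      }
      a2 <- cos(phi) * e1 + sin(phi) * e2
      cells[[i]] <- cell_record(sprintf("cell_%03d", i), pos[i, ])
      cells[[i]]$true_a1 <- canonical_axis(a1)
      cells[[i]]$true_a2 <- canonical_axis(a2)
      if (make_meshes) {
        meshes[[i]] <- generate_cell_mesh(
          pattern = config$apical_pattern, axis = a1, ring_axis = a2,
          noise_kappa = config$noise_kappa,
          mesh_subdivisions = config$mesh_subdivisions,
          radius = config$cell_radius, mix_weight = config$mix_weight,
          basal_complement = config$basal_complement,
          cell_id = cells[[i]]$cell_id)
        meshes[[i]]$vertices <- sweep(meshes[[i]]$vertices, 2, pos[i, ], "+")
        meshes[[i]]$center <- meshes[[i]]$center + pos[i, ]
      }
    }

    skeleton <- generate_sinusoid_skeleton(charges, L, margin,
                                           kappa = config$sinusoid_kappa,
                                           seg_length = 5,
                                           n_chains = max(10, config$n_cells %/% 3),
                                           steps = 12)
    structure(list(cells = cells, meshes = meshes, cv_mesh = cv, pv_mesh = pv,
                   charges = charges, skeleton = skeleton, J = J,
                   config = config),
              class = "synthetic_lobule")
  })
}

## chains of segments with Watson-distributed orientations about J
generate_sinusoid_skeleton <- function(charges, extent, margin, kappa,
                                       seg_length = 5, n_chains = 40,
                                       steps = 12) {
  nodes <- list(); segments <- list()
  for (ch in seq_len(n_chains)) {
    p <- stats::runif(3, margin, extent - margin)
    nodes[[length(nodes) + 1]] <- p
    head_idx <- length(nodes)
    prev_dir <- NULL
    for (s in seq_len(steps)) {
      g <- tryCatch(reference_direction(matrix(p, 1), charges,
                                        exclusion_radius = 0.5),
                    error = function(e) NULL)
      if (is.null(g) || g$stagnant[1]) break
      d <- as.numeric(rwatson(1, g$J[1, ], kappa))
      ## keep the chain advancing (axes are sign-free)
      if (!is.null(prev_dir) && sum(d * prev_dir) < 0) d <- -d
      p2 <- p + seg_length * d
      if (any(p2 < 0) || any(p2 > extent)) break
      nodes[[length(nodes) + 1]] <- p2
      segments[[length(segments) + 1]] <- c(head_idx, length(nodes))
      head_idx <- length(nodes)
      p <- p2
      prev_dir <- d
    }
  }
  if (length(segments) == 0)
    stop("sinusoid skeleton generation produced no segments")
  network_skeleton(do.call(rbind, nodes), do.call(rbind, segments))
}

#' Generate layered density grids
#'
#' Alternating slabs perpendicular to an in-plane layer-normal direction:
#' sinusoid slabs of width `sinusoid_width` and hepatocyte slabs filling the
#' rest of each `layer_spacing` period, with each layer's position shifted
#' by an independent uniform phase of amplitude
#' `layer_jitter * layer_spacing`. Hepatocyte and sinusoid grids are exact
#' complements (voxelwise sum 1); the bile-canaliculi grid is a narrow band
#' centered within each hepatocyte slab. The pattern is constant along z.
#'
#' @param config a [lobule_config].
#' @param extent length-3 grid extent (um); default
#'   `c(150, 150, 60)`, a mid-lobule region of interest.
#' @param layer_normal length-2 unit vector (xy plane) along which layers
#'   stack; default `c(0, 1)` (layers stack along y, perpendicular to the
#'   CV-PV axis).
#' @param bc_width bile-canaliculi band width (um); default 2.
#' @param seed optional integer overriding `config$seed`.
#' @return list with [density_grid]s `hepatocyte`, `sinusoid`, `bc`, plus
#'   `layer_normal`.
#' @export
generate_layered_grid <- function(config = lobule_config(),
                                  extent = c(150, 150, 60),
                                  layer_normal = c(0, 1), bc_width = 2,
                                  seed = NULL) {
  stopifnot(inherits(config, "lobule_config"))
  vs <- config$voxel_size
  spacing <- config$layer_spacing
  w <- config$sinusoid_width
  if (spacing <= 2 * vs) stop("layer_spacing must exceed two voxels")
  if (config$layer_jitter >= 0.5)
    warning("layer_jitter >= 0.5: adjacent layers may merge")
  layer_normal <- as.numeric(layer_normal)
  layer_normal <- layer_normal / sqrt(sum(layer_normal^2))
  if (is.null(seed)) seed <- config$seed
  with_local_seed(seed, {
    n <- pmax(1L, as.integer(round(extent / vs)))
    xc <- (seq_len(n[1]) - 0.5) * vs
    yc <- (seq_len(n[2]) - 0.5) * vs
    ## signed coordinate along the layer normal for every (x, y) voxel
    coord <- outer(xc * layer_normal[1], yc * layer_normal[2], "+")
    ilayer <- floor(coord / spacing)
    lrange <- range(ilayer)
    layer_ids <- lrange[1]:lrange[2]
    jit <- stats::runif(length(layer_ids), -1, 1) *
      config$layer_jitter * spacing
    names(jit) <- as.character(layer_ids)
    in_band <- function(center_offset, width) {
      ## voxel belongs to a band of the given width anchored at
      ## layer_start + jitter + center_offset, checked against the three
      ## nearest layers since jitter can cross period boundaries
      member <- matrix(FALSE, n[1], n[2])
      for (d in -1:1) {
        li <- ilayer + d
        jd <- jit[as.character(li)]
        jd[is.na(jd)] <- 0
        start <- li * spacing + matrix(jd, n[1], n[2]) + center_offset
        member <- member | (coord >= start & coord < start + width)
      }
      member
    }
    sin2d <- in_band(0, w)
    bc2d <- in_band(w + (spacing - w - bc_width) / 2, bc_width)
    rep3d <- function(m) array(as.numeric(m), c(n[1], n[2], n[3]))
    list(hepatocyte = density_grid(rep3d(!sin2d), vs),
         sinusoid = density_grid(rep3d(sin2d), vs),
         bc = density_grid(rep3d(bc2d), vs),
         layer_normal = layer_normal)
  })
}
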