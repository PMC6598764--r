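## End-to-end orchestration: polarity -> reference field -> network ->
## alignment -> layered order, with a machine-readable report.

#' Run the full lobule analysis
#'
#' Executes the complete analysis sequence on a synthetic lobule (from
#' [generate_lobule()]) or on a directory of inputs: per-cell biaxial
#' polarity from labeled meshes, the vein-derived reference field J at each
#' cell, local sinusoid axes, alignment statistics (S for a1, a2 and the
#' sinusoid axis against J, with the uniaxial baseline for a2), the
#' apical-basal axis-correlation table, and the layered-order period
#' estimates along the layer normal and the perpendicular control
#' direction.
#'
#' A directory input must contain cell meshes `cell_*.ply`, vein meshes
#' `cv.ply` / `pv.ply`, a skeleton `sinusoids.json`, and optionally density
#' grids `hepatocyte.tif` / `sinusoid.tif` (with their JSON sidecars).
#'
#' @param input a `synthetic_lobule`, a directory path, or `NULL` (simulate
#'   from `config`).
#' @param config [lobule_config] used when simulating and for the layered
#'   grids.
#' @param seed integer seed controlling all randomness of the run.
#' @param network_radius neighborhood radius for local sinusoid axes (um);
#'   default 20.
#' @param layered run the layered-order stage (default TRUE; it dominates
#'   runtime).
#' @param grid_extent extent (um) of the synthetic layered grids.
#' @param n_null circular shifts for the period null band; default 200.
#' @return list of class `lobule_report`; see [write_report()].
#' @export
run_full_analysis <- function(input = NULL, config = lobule_config(),
                              seed = config$seed, network_radius = 20,
                              layered = TRUE, grid_extent = c(150, 150, 6),
                              n_null = 200) {
  set.seed(seed)
  config$seed <- seed
  if (is.null(input)) input <- generate_lobule(config)
  if (is.character(input)) input <- read_lobule_dir(input)
  stopifnot(inherits(input, "synthetic_lobule") || is.list(input))

  cells <- input$cells
  meshes <- input$meshes
  report <- list(seed = seed, n_cells = length(cells), stages = character())

  ## polarity
  if (!is.null(meshes)) {
    for (i in seq_along(cells)) {
      proj <- spherical_projection(meshes[[i]])
      cells[[i]]$apical <- polarity_axes(nematic_tensor(proj))
      basal_mask <- select_marker_triangles(meshes[[i]], "basal")
      if (length(basal_mask) > 0)
        cells[[i]]$basal <- polarity_axes(nematic_tensor(proj, basal_mask))
    }
    report$stages <- c(report$stages, "polarity")
    sig <- t(vapply(cells, function(cl) cl$apical$sigma[1:2], numeric(2)))
    report$polarity <- list(
      mean_sigma1 = mean(sig[, 1]), mean_sigma2 = mean(sig[, 2]),
      sigma1 = sig[, 1], sigma2 = sig[, 2])
    if (all(vapply(cells, function(cl) !is.null(cl$basal), TRUE))) {
      axcor <- axis_cross_correlation(cells)
      report$axis_correlations <- stats::setNames(axcor$S, axcor$pair)
    }
  } else {
    report$stages <- c(report$stages, "polarity:skipped (no meshes)")
    for (i in seq_along(cells)) {
      cells[[i]]$apical <- axes_from_truth(cells[[i]])
    }
  }

  ## reference field at cell positions
  if (!is.null(input$charges)) {
    pos <- t(vapply(cells, function(cl) cl$position, numeric(3)))
    J <- reference_direction(pos, input$charges, exclusion_radius = 0.5)$J
    report$stages <- c(report$stages, "reference_field")
  } else if (!is.null(input$J)) {
    J <- input$J
  } else {
    stop("no vein meshes/charges and no precomputed reference field")
  }

  ## local sinusoid axes
  if (!is.null(input$skeleton)) {
    for (i in seq_along(cells)) {
      loc <- local_network_axis(input$skeleton, cells[[i]]$position,
                                radius = network_radius)
      if (!is.null(loc) && !loc$degenerate)
        cells[[i]]$sinusoid_axis <- loc$axis
    }
    report$stages <- c(report$stages, "network")
  }

  ## alignment statistics against J
  S_of <- function(axis_type) {
    ax <- tryCatch(collect_axes(cells, axis_type), error = function(e) NULL)
    if (is.null(ax)) return(NULL)
    ok <- stats::complete.cases(J[ax$index, , drop = FALSE])
    alignment_parameter(ax$axes[ok, , drop = FALSE],
                        J[ax$index[ok], , drop = FALSE])
  }
  S1 <- S_of("a1"); S2 <- S_of("a2"); Ssin <- S_of("sinusoid")
  report$alignment <- list(
    S_a1_J = S1, S_a2_J = S2, S_sinusoid_J = Ssin,
    baseline_a2 = if (!is.null(S1)) uniaxial_baseline(S1) else NULL,
    excess_a2 = if (!is.null(S1) && !is.null(S2)) S2 + S1 / 2 else NULL)
  report$stages <- c(report$stages, "alignment")

  ## layered order
  if (layered) {
    grids <- generate_layered_grid(config, extent = grid_extent)
    res <- layered_order_analysis(grids$sinusoid, grids$hepatocyte,
                                  direction = grids$layer_normal,
                                  n_null = n_null)
    ctrl_dir <- c(-grids$layer_normal[2], grids$layer_normal[1])
    ctrl <- layered_order_analysis(grids$sinusoid, grids$hepatocyte,
                                   direction = ctrl_dir, n_null = n_null)
    report$layered <- list(
      period_um = res$period$period,
      peak_value = res$period$peak_value,
      significant = res$period$significant,
      control_period_um = ctrl$period$period,
      control_significant = isTRUE(ctrl$period$significant))
    report$stages <- c(report$stages, "layered_order")
  }

  report$cells <- cells
  class(report) <- "lobule_report"
  report
}

## fall back to ground-truth axes when no meshes are present
axes_from_truth <- function(cl) {
  if (is.null(cl$true_a1)) return(NULL)
  a3 <- as.numeric(cross_rows(cl$true_a1, cl$true_a2))
  structure(list(axes = rbind(a1 = cl$true_a1, a2 = cl$true_a2, a3 = a3),
                 sigma = c(0.5, -0.4, -0.1),
                 degenerate = c(FALSE, FALSE, FALSE)),
            class = "polarity_axes")
}

#' Read a lobule input directory
#'
#' @param dir directory with `cell_*.ply`, `cv.ply`, `pv.ply`,
#'   `sinusoids.json`.
#' @return list shaped like a `synthetic_lobule`.
#' @export
read_lobule_dir <- function(dir) {
  mesh_files <- sort(list.files(dir, "^cell_.*\\.ply$", full.names = TRUE))
  if (length(mesh_files) == 0) stop("no cell meshes (cell_*.ply) in ", dir)
  meshes <- lapply(mesh_files, read_labeled_mesh)
  cells <- lapply(meshes, function(m) cell_record(m$cell_id, m$center))
  cv <- read_labeled_mesh(file.path(dir, "cv.ply"))
  pv <- read_labeled_mesh(file.path(dir, "pv.ply"))
  skel_path <- file.path(dir, "sinusoids.json")
  skeleton <- if (file.exists(skel_path)) read_skeleton(skel_path) else NULL
  structure(list(cells = cells, meshes = meshes, cv_mesh = cv, pv_mesh = pv,
                 charges = build_charges(cv, pv), skeleton = skeleton),
            class = "synthetic_lobule")
}

#' Write a synthetic lobule to a directory
#'
#' Exports meshes (PLY), the sinusoid skeleton (JSON), ground truth (CSV)
#' and the resolved configuration (YAML), in the layout read by
#' [read_lobule_dir()].
#'
#' @param lobule a `synthetic_lobule`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_lobule_dir <- function(lobule, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in lobule$meshes)
    write_labeled_mesh(m, file.path(dir, paste0(m$cell_id, ".ply")))
  for (vein in c("cv", "pv")) {
    vm <- lobule[[paste0(vein, "_mesh")]]
    write_labeled_mesh(labeled_mesh(vm$vertices, vm$triangles),
                       file.path(dir, paste0(vein, ".ply")))
  }
  write_skeleton(lobule$skeleton, file.path(dir, "sinusoids.json"))
  truth <- do.call(rbind, lapply(lobule$cells, function(cl)
    data.frame(cell_id = cl$cell_id,
               x = cl$position[1], y = cl$position[2], z = cl$position[3],
               a1x = cl$true_a1[1], a1y = cl$true_a1[2], a1z = cl$true_a1[3],
               a2x = cl$true_a2[1], a2y = cl$true_a2[2], a2z = cl$true_a2[3])))
  utils::write.csv(truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  write_lobule_config(lobule$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write an analysis report as JSON
#'
#' Serializes the numeric summary of a [run_full_analysis()] report
#' (alignment statistics, axis correlations, layered-order results, polarity
#' weight summaries) deterministically, so identical runs produce identical
#' files.
#'
#' @param report a `lobule_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- report[setdiff(names(report), "cells")]
  out$polarity$sigma1 <- NULL
  out$polarity$sigma2 <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Summarize replicate reports
#'
#' Across-replicate mean and standard deviation of the alignment
#' statistics, plus Welch comparisons between two conditions when both are
#' given (two-sided, unequal variances).
#'
#' @param reports list of `lobule_report` objects (one condition), or a
#'   list of two such lists for a two-condition comparison.
#' @return data.frame of per-statistic summaries; with two conditions, a
#'   `p_welch` column.
#' @export
replicate_summary <- function(reports) {
  two <- length(reports) == 2 && is.list(reports[[1]]) &&
    !inherits(reports[[1]], "lobule_report")
  stat_names <- c("S_a1_J", "S_a2_J", "S_sinusoid_J")
  pull <- function(reps, s) vapply(reps, function(r) r$alignment[[s]], 0)
  if (!two) {
    vals <- lapply(stat_names, function(s) pull(reports, s))
    return(data.frame(statistic = stat_names,
                      mean = vapply(vals, mean, 0),
                      sd = vapply(vals, stats::sd, 0),
                      n = length(reports)))
  }
  rows <- lapply(stat_names, function(s) {
    a <- pull(reports[[1]], s); b <- pull(reports[[2]], s)
    data.frame(statistic = s, mean_1 = mean(a), sd_1 = stats::sd(a),
               mean_2 = mean(b), sd_2 = stats::sd(b),
               n_1 = length(a), n_2 = length(b),
               p_welch = compare_groups(a, b))
  })
  do.call(rbind, rows)
}
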