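## DensityGrid (3D voxel array) and DensityImage (2D projection).
## Convention: 0-based voxel indexing with the center of voxel (i, j, k) at
## origin + (index + 0.5) * voxel_size, isotropic voxels.

#' Construct a 3D density grid
#'
#' @param values non-negative 3D numeric array (x, y, z order).
#' @param voxel_size isotropic voxel edge length (um); default 0.3.
#' @param origin world position (um) of the grid corner.
#' @return object of class `density_grid`.
#' @export
density_grid <- function(values, voxel_size = 0.3, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3) stop("density grid requires a 3D array")
  if (length(voxel_size) == 3) {
    if (diff(range(voxel_size)) > 1e-9)
      stop("anisotropic voxels are not supported; isotropic voxel size required")
    voxel_size <- voxel_size[1]
  }
  if (voxel_size <= 0) stop("voxel_size must be positive")
  if (any(values < 0)) stop("density values must be non-negative")
  structure(list(values = values, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "density_grid")
}

#' Construct a 2D density image
#' @param values 2D numeric array.
#' @param pixel_size pixel edge length (um).
#' @return object of class `density_image`.
#' @export
density_image <- function(values, pixel_size) {
  if (length(dim(values)) != 2) stop("density image requires a 2D array")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(values = values, pixel_size = pixel_size),
            class = "density_image")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid: %d x %d x %d voxels at %.3g um (%.1f x %.1f x %.1f um)\n",
              d[1], d[2], d[3], x$voxel_size,
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a density grid to multi-page TIFF
#'
#' One 32-bit float page per z-slice. Because baseline TIFF metadata cannot
#' carry the voxel size or arbitrary value ranges reliably, a JSON sidecar
#' (`<path>.json`) stores `voxel_size`, `origin` and the linear `scale`
#' used to map values into the [0, 1] sample range.
#'
#' @param grid a [density_grid].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_density_grid <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  scale <- max(grid$values)
  if (scale == 0) scale <- 1
  d <- dim(grid$values)
  pages <- lapply(seq_len(d[3]), function(k) grid$values[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE,
                  compression = "none")
  jsonlite::write_json(list(voxel_size = grid$voxel_size,
                            origin = grid$origin, scale = scale,
                            dim = d),
                       sidecar_path(path), digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a density grid from multi-page TIFF
#'
#' Reads a stack written by [write_density_grid()]. If the JSON sidecar with
#' the voxel size is missing, falls back to `default_voxel_size` with a
#' warning; a sidecar declaring anisotropic voxels is an error.
#'
#' @param path TIFF path.
#' @param default_voxel_size fallback voxel size (um); default 0.3.
#' @return a [density_grid].
#' @export
read_density_grid <- function(path, default_voxel_size = 0.3) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2)
    stop("expected single-channel 2D pages in density TIFF")
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::fromJSON(sp)
    voxel_size <- meta$voxel_size
    origin <- if (is.null(meta$origin)) c(0, 0, 0) else meta$origin
    scale <- if (is.null(meta$scale)) 1 else meta$scale
  } else {
    warning("no voxel-size metadata found; assuming ",
            default_voxel_size, " um voxels")
    voxel_size <- default_voxel_size
    origin <- c(0, 0, 0)
    scale <- 1
  }
  d <- dim(pages[[1]])
  values <- array(0, c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) values[, , k] <- pages[[k]] * scale
  density_grid(values, voxel_size = voxel_size, origin = origin)
}

#' World coordinates of voxel centers along one grid dimension
#' @param grid a [density_grid].
#' @param dim_index 1, 2 or 3.
#' @return numeric vector of center coordinates (um).
#' @export
voxel_centers <- function(grid, dim_index) {
  n <- dim(grid$values)[dim_index]
  grid$origin[dim_index] + (seq_len(n) - 0.5) * grid$voxel_size
}
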