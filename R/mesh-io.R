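## Mesh readers/writers. Supported formats: PLY (ascii and
## binary_little_endian) and OFF, with the membrane label stored as a
## per-vertex integer property named "label" (PLY) or as a fourth numeric
## column on each OFF vertex line. Label codes follow [MEMBRANE_LABELS].

#' Read a labeled surface mesh
#'
#' Reads a triangle mesh with per-vertex membrane labels from PLY (ascii or
#' binary little-endian; label as a vertex property named `label`) or OFF
#' (label as a fourth value on each vertex line). The format is inferred
#' from the file extension.
#'
#' @param path path to a `.ply` or `.off` file.
#' @param cell_id identifier for the mesh; defaults to the file stem.
#' @return a [labeled_mesh].
#' @export
read_labeled_mesh <- function(path, cell_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(cell_id))
    cell_id <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(tools::file_ext(path))
  parsed <- switch(ext,
    ply = read_ply(path),
    off = read_off(path),
    stop("cannot infer mesh format from extension '", ext,
         "'; supported: ply, off"))
  labeled_mesh(parsed$vertices, parsed$triangles, parsed$labels,
               cell_id = cell_id)
}

#' Write a labeled surface mesh
#'
#' Positions are stored as 64-bit doubles so a write/read cycle is lossless.
#'
#' @param mesh a [labeled_mesh].
#' @param path output path ending in `.ply` or `.off`.
#' @param binary for PLY, write `binary_little_endian` instead of ascii.
#' @return `path`, invisibly.
#' @export
write_labeled_mesh <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "labeled_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ply = write_ply(mesh, path, binary = binary),
    off = write_off(mesh, path),
    stop("cannot infer mesh format from extension '", ext,
         "'; supported: ply, off"))
  invisible(path)
}

## ---- PLY ----

read_ply_header <- function(con) {
  lines <- character()
  repeat {
    bytes <- raw()
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) stop("unexpected end of PLY header")
      if (b == as.raw(10)) break
      bytes <- c(bytes, b)
    }
    line <- sub("\r$", "", rawToChar(bytes))
    lines <- c(lines, line)
    if (line == "end_header") break
  }
  lines
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- read_ply_header(con)
  if (header[1] != "ply") stop("not a PLY file: ", path)
  fmt <- sub("^format ", "", grep("^format ", header, value = TRUE)[1])
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format: ", fmt)

  ## parse elements and their properties
  elements <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      elements[[cur]]$props[[length(elements[[cur]]$props) + 1]] <- tok[-1]
    }
  }
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY file lacks vertex or face elements")
  vprops <- vapply(elements$vertex$props, function(p) p[length(p)], "")
  vtypes <- vapply(elements$vertex$props, function(p) p[1], "")
  if (!"label" %in% vprops)
    stop("mesh file has no per-vertex 'label' attribute: ", path)
  needed <- c("x", "y", "z", "label")
  if (!all(c("x", "y", "z") %in% vprops))
    stop("PLY vertex element lacks x/y/z properties")
  nv <- elements$vertex$count
  nf <- elements$face$count

  type_size <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1,
                 short = 2, ushort = 2, int16 = 2, uint16 = 2,
                 int = 4, uint = 4, int32 = 4, uint32 = 4,
                 float = 4, float32 = 4, double = 8, float64 = 8)
  if (binary) {
    sizes <- type_size[vtypes]
    if (anyNA(sizes)) stop("unsupported PLY vertex property type")
    stride <- sum(sizes)
    raw_v <- readBin(con, "raw", nv * stride)
    if (length(raw_v) < nv * stride) stop("truncated PLY vertex data")
    offs <- cumsum(c(0, sizes))
    read_col <- function(i) {
      sel <- as.vector(outer(seq_len(sizes[i]) + offs[i],
                             (seq_len(nv) - 1) * stride, "+"))
      bytes <- raw_v[sel]
      tp <- vtypes[i]
      if (tp %in% c("float", "float32"))
        readBin(bytes, "double", nv, size = 4, endian = "little")
      else if (tp %in% c("double", "float64"))
        readBin(bytes, "double", nv, size = 8, endian = "little")
      else if (sizes[i] == 1)
        as.integer(readBin(bytes, "integer", nv, size = 1, signed = FALSE))
      else
        readBin(bytes, "integer", nv, size = sizes[i], endian = "little")
    }
    cols <- lapply(seq_along(vprops), read_col)
    names(cols) <- vprops
    vertices <- cbind(cols$x, cols$y, cols$z)
    labels <- as.integer(cols$label)
    ## faces: assume "list uchar int" (as written by this package)
    fraw <- readBin(con, "raw", nf * 13)
    if (length(fraw) < nf * 13) stop("truncated PLY face data")
    fm <- matrix(fraw, nrow = 13)
    counts <- as.integer(fm[1, ])
    if (any(counts != 3L)) stop("mesh has non-triangular faces")
    idx <- readBin(as.raw(fm[2:13, ]), "integer", nf * 3, size = 4,
                   endian = "little")
    triangles <- matrix(idx, ncol = 3, byrow = TRUE) + 1L
  } else {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    vlines <- txt[seq_len(nv)]
    flines <- txt[nv + seq_len(nf)]
    vdat <- matrix(scan(text = vlines, quiet = TRUE), nrow = nv, byrow = TRUE)
    colnames(vdat) <- vprops
    vertices <- vdat[, c("x", "y", "z"), drop = FALSE]
    labels <- as.integer(vdat[, "label"])
    ftok <- strsplit(trimws(flines), "\\s+")
    counts <- vapply(ftok, function(t) as.integer(t[1]), 0L)
    if (any(counts != 3L)) stop("mesh has non-triangular faces")
    triangles <- t(vapply(ftok, function(t) as.integer(t[2:4]), integer(3))) + 1L
  }
  dimnames(vertices) <- NULL
  list(vertices = vertices, triangles = triangles, labels = labels)
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              sprintf("comment cell_id %s", mesh$cell_id),
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              "property uchar label",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  tri0 <- t(mesh$triangles) - 1L
  if (binary) {
    coord_raw <- writeBin(as.vector(t(mesh$vertices)), raw(), size = 8,
                          endian = "little")
    lab_raw <- as.raw(mesh$labels)
    vraw <- as.raw(rbind(matrix(coord_raw, nrow = 24), matrix(lab_raw, nrow = 1)))
    writeBin(as.vector(vraw), con)
    idx_raw <- writeBin(as.integer(tri0), raw(), size = 4, endian = "little")
    fraw <- as.raw(rbind(matrix(rep(as.raw(3), nf), nrow = 1),
                         matrix(idx_raw, nrow = 12)))
    writeBin(as.vector(fraw), con)
  } else {
    vlines <- sprintf("%.17g %.17g %.17g %d",
                      mesh$vertices[, 1], mesh$vertices[, 2],
                      mesh$vertices[, 3], mesh$labels)
    flines <- sprintf("3 %d %d %d", tri0[1, ], tri0[2, ], tri0[3, ])
    writeLines(c(vlines, flines), con, sep = "\n")
  }
}

## ---- OFF ----

read_off <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt)) & !grepl("^#", txt)]
  if (toupper(trimws(txt[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(txt[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtok <- strsplit(trimws(txt[2 + seq_len(nv)]), "\\s+")
  ncols <- unique(lengths(vtok))
  if (length(ncols) != 1 || !ncols %in% c(3L, 4L))
    stop("malformed OFF vertex lines")
  if (ncols == 3L)
    stop("mesh file has no per-vertex 'label' attribute: ", path)
  vdat <- matrix(as.numeric(unlist(vtok)), nrow = nv, byrow = TRUE)
  ftok <- strsplit(trimws(txt[2 + nv + seq_len(nf)]), "\\s+")
  fcount <- vapply(ftok, function(t) as.integer(t[1]), 0L)
  if (any(fcount != 3L)) stop("mesh has non-triangular faces")
  triangles <- t(vapply(ftok, function(t) as.integer(t[2:4]), integer(3))) + 1L
  list(vertices = vdat[, 1:3, drop = FALSE], triangles = triangles,
       labels = as.integer(vdat[, 4]))
}

write_off <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  tri0 <- t(mesh$triangles) - 1L
  lines <- c("OFF",
             sprintf("%d %d 0", nv, nf),
             sprintf("%.17g %.17g %.17g %d",
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3], mesh$labels),
             sprintf("3 %d %d %d", tri0[1, ], tri0[2, ], tri0[3, ]))
  writeLines(lines, path)
}
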