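#' Per-cell analysis record
#'
#' Bundles one cell's position with its measured (or ground-truth) polarity
#' axes and, when available, the preferred axis of the surrounding sinusoid
#' network.
#'
#' @param cell_id identifier.
#' @param position length-3 cell center (um).
#' @param apical,basal `polarity_axes` objects (or `NULL`).
#' @param sinusoid_axis local sinusoid preferred axis (unit length-3) or
#'   `NULL` when no network segments were found near the cell.
#' @return object of class `cell_record`.
#' @export
cell_record <- function(cell_id, position, apical = NULL, basal = NULL,
                        sinusoid_axis = NULL) {
  position <- as.numeric(position)
  if (length(position) != 3 || any(!is.finite(position)))
    stop("position must be a finite length-3 vector")
  structure(list(cell_id = cell_id, position = position, apical = apical,
                 basal = basal, sinusoid_axis = sinusoid_axis),
            class = "cell_record")
}

#' Extract one axis type from a list of cell records
#'
#' Returns the requested axis for every cell where it is defined and
#' non-degenerate, along with the cell positions and indices.
#'
#' @param cells list of [cell_record] objects.
#' @param axis_type one of `"a1"`, `"a2"`, `"b1"`, `"b2"`, `"sinusoid"`.
#' @return list with `axes` (n x 3), `positions` (n x 3), `index`.
#' @export
collect_axes <- function(cells,
                         axis_type = c("a1", "a2", "b1", "b2", "sinusoid")) {
  axis_type <- match.arg(axis_type)
  get1 <- function(cl) {
    if (axis_type == "sinusoid") {
      if (is.null(cl$sinusoid_axis)) return(NULL)
      return(cl$sinusoid_axis)
    }
    src <- if (substr(axis_type, 1, 1) == "a") cl$apical else cl$basal
    if (is.null(src)) return(NULL)
    i <- as.integer(substr(axis_type, 2, 2))
    if (src$degenerate[i]) return(NULL)
    src$axes[i, ]
  }
  vals <- lapply(cells, get1)
  keep <- !vapply(vals, is.null, TRUE)
  if (!any(keep))
    stop("no cell provides a non-degenerate '", axis_type, "' axis")
  list(axes = do.call(rbind, vals[keep]),
       positions = t(vapply(cells[keep], function(cl) cl$position, numeric(3))),
       index = which(keep))
}
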