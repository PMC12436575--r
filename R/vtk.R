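#' Write a mesh with fields as a legacy VTK unstructured grid
#'
#' ASCII VTK legacy format, readable by ParaView and meshio. Cell data
#' (per-element fields such as region, density or strain energy density)
#' and point data (such as displacement) are optional.
#'
#' @param mesh An `fe_mesh`.
#' @param file Output path (conventionally `.vtk`).
#' @param cell_data Named list of per-element vectors (or an `n x k` matrix
#'   per entry for vector fields).
#' @param point_data Named list of per-node vectors/matrices.
#' @export
write_vtk <- function(mesh, file, cell_data = NULL, point_data = NULL) {
  stopifnot(inherits(mesh, "fe_mesh"))
  con <- file(file, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  nel <- nrow(mesh$elems)
  writeLines(c("# vtk DataFile Version 3.0",
               "osteogrow field snapshot", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  pts <- mesh$nodes
  if (ncol(pts) == 2) pts <- cbind(pts, 0)
  writeLines(paste(pts[, 1], pts[, 2], pts[, 3]), con)
  npe <- ncol(mesh$elems)
  writeLines(sprintf("CELLS %d %d", nel, nel * (npe + 1)), con)
  writeLines(paste(npe, apply(mesh$elems - 1L, 1, paste, collapse = " ")),
             con)
  ctype <- switch(mesh$elem_type, tri = 5L, quad = 9L, hex = 12L)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(as.character(rep(ctype, nel)), con)
  write_fields <- function(data, count) {
    for (nm in names(data)) {
      v <- data[[nm]]
      if (is.matrix(v) && ncol(v) >= 2) {
        if (ncol(v) == 2) v <- cbind(v, 0)
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
      } else {
        if (is.character(v) || is.factor(v)) v <- as.integer(factor(v))
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(as.character(as.numeric(v)), con)
      }
    }
  }
  if (!is.null(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", nel), con)
    write_fields(cell_data, nel)
  }
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    write_fields(point_data, n)
  }
  invisible(file)
}
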