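#' Write a mesh (with optional fields) as a legacy-ASCII VTK file
#'
#' Unstructured-grid writer for inspection in ParaView-family tools: the
#' triangulation plus any point and cell data arrays.
#'
#' @param mesh an `laa_mesh`.
#' @param file output path (conventionally `.vtk`).
#' @param point_data named list of numeric vectors on vertices.
#' @param cell_data named list of numeric vectors on cells.
#' @export
write_mesh_vtk <- function(mesh, file, point_data = NULL, cell_data = NULL) {
  stopifnot(inherits(mesh, "laa_mesh"))
  n <- nrow(mesh$vertices); m <- nrow(mesh$triangles)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "laastasis mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$vertices[, 1L],
                     mesh$vertices[, 2L]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1L] - 1L,
                     mesh$triangles[, 2L] - 1L, mesh$triangles[, 3L] - 1L),
             con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  wr <- function(data, header) {
    writeLines(header, con)
    for (nm in names(data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", as.numeric(data[[nm]])), con)
    }
  }
  if (!is.null(point_data) && length(point_data))
    wr(point_data, sprintf("POINT_DATA %d", n))
  if (!is.null(cell_data) && length(cell_data))
    wr(cell_data, sprintf("CELL_DATA %d", m))
  invisible(file)
}

#' Write a stasis summary as JSON
#'
#' @param summary a `stasis_summary`.
#' @param file output path.
#' @param provenance optional named list (config hash, seed) stored alongside.
#' @export
write_summary_json <- function(summary, file, provenance = NULL) {
  stopifnot(inherits(summary, "stasis_summary"))
  x <- unclass(summary)
  x$centerline_velocity <- as.list(x$centerline_velocity)
  x$centerline_ssr <- as.list(x$centerline_ssr)
  if (!is.null(provenance)) x$provenance <- provenance
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Write a waveform table as CSV
#'
#' @param wf an [mitral_waveform()].
#' @param file output path.
#' @param dt sampling interval (s).
#' @export
write_waveform_csv <- function(wf, file, dt = 5e-4) {
  utils::write.csv(waveform_table(wf, dt), file, row.names = FALSE)
  invisible(file)
}
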