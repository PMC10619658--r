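## Field output: legacy ASCII VTK image data and CSV probe logs.

#' Write fluid fields as a legacy VTK structured-points file
#'
#' Scalars (density, eddy viscosity, vorticity) and the velocity vector on
#' the uniform lattice, readable by ParaView and pyvista.
#'
#' @param path output file (.vtk).
#' @param dims grid dimensions (nx, ny, nz).
#' @param dx lattice spacing (m).
#' @param scalars named list of length-n numeric vectors.
#' @param vectors named list of n x 3 matrices.
#' @return The path, invisibly.
#' @export
write_vtk_image <- function(path, dims, dx, scalars = list(),
                            vectors = list()) {
  n <- prod(dims)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "canopyflow fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("ORIGIN %g %g %g", dx / 2, dx / 2, dx / 2),
               sprintf("SPACING %g %g %g", dx, dx, dx),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
               con)
    writeLines(format(scalars[[nm]], digits = 9, scientific = TRUE,
                      trim = TRUE), con)
  }
  for (nm in names(vectors)) {
    writeLines(sprintf("VECTORS %s double", nm), con)
    v <- vectors[[nm]]
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  }
  invisible(path)
}

#' Export a simulation record's final fluid frame to VTK
#' @param record a `simulation_record` with a stored fluid frame.
#' @param path output .vtk path.
#' @return The path, invisibly.
#' @export
export_fluid_vtk <- function(record, path) {
  frames <- Filter(function(fr) !is.null(fr$u), record$frames)
  if (length(frames) == 0) stop("record stored no fluid fields")
  fr <- frames[[length(frames)]]
  dx <- record$scaling$dx
  write_vtk_image(path, record$dims, dx,
                  scalars = list(
                    rho = fr$rho,
                    vorticity = vorticity(fr$u, record$dims, dx,
                                          periodic = FALSE)),
                  vectors = list(velocity = fr$u))
}
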