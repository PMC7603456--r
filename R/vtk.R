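# Minimal legacy-ASCII VTK polydata writer for visualization interchange.
# Only what the package needs to emit: a point cloud / polyline with named
# scalar and vector point-data arrays.

#' Write points with attached fields as legacy ASCII VTK polydata
#'
#' @param points Numeric matrix (n x 3) of coordinates.
#' @param path Output `.vtk` file path.
#' @param scalars Named list of length-n numeric vectors (optional).
#' @param vectors Named list of n x 3 numeric matrices (optional).
#' @param as_polyline If `TRUE`, connect the points into a single polyline
#'   (useful for meridian profiles).
#' @return `path`, invisibly.
#' @export
write_vtk_points <- function(points, path, scalars = list(),
                             vectors = list(), as_polyline = FALSE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  n <- nrow(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "fsgr export", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(apply(points, 1, function(p) paste(sprintf("%.10g", p),
                                                collapse = " ")), con)
  if (as_polyline) {
    writeLines(sprintf("LINES 1 %d", n + 1), con)
    writeLines(paste(c(n, seq_len(n) - 1), collapse = " "), con)
  } else {
    writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
    writeLines(sprintf("1 %d", seq_len(n) - 1), con)
  }
  if (length(scalars) || length(vectors)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", scalars[[nm]]), con)
    }
    for (nm in names(vectors)) {
      v <- as.matrix(vectors[[nm]])
      stopifnot(nrow(v) == n, ncol(v) == 3)
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(v, 1, function(p) paste(sprintf("%.10g", p),
                                               collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Export a geometry meridian (optionally with an equilibrium field) to VTK
#'
#' @param geometry An [build_geometry()] result.
#' @param path Output `.vtk` path.
#' @param eq Optional [solve_equilibrium()] field; its stretches and current
#'   radius are attached as point data.
#' @return `path`, invisibly.
#' @export
export_geometry_vtk <- function(geometry, path, eq = NULL) {
  stopifnot(inherits(geometry, "ideal_geometry"))
  pts <- geometry$points
  xyz <- cbind(pts$r_ref, 0, pts$z)
  scal <- list(u = pts$u, k1 = pts$k1, r2 = pts$r2)
  if (!is.null(eq)) {
    xyz <- cbind(eq$r_cur, 0, pts$z)
    scal <- c(scal, list(lam_t = eq$lam_t, lam_p = eq$lam_p,
                         J_m = eq$J_m, J_a = eq$J_a))
  }
  write_vtk_points(xyz, path, scalars = scal, as_polyline = TRUE)
}
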