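#' Write a flow snapshot as a legacy-VTK structured grid
#'
#' ASCII "STRUCTURED_GRID" legacy format readable by ParaView/VisIt:
#' cell-center coordinates as points, with velocity, pressure and any
#' extra scalar fields attached as point data.
#'
#' @param state a [flow_state()].
#' @param grid the flow grid.
#' @param file output path (`.vtk`).
#' @param extra named list of additional `nx x ny` matrices (e.g.
#'   vorticity, Q).
#' @return the file path, invisibly.
#' @export
write_vtk <- function(state, grid, file, extra = list()) {
  xc <- grid$axes[[1]]$xc; yc <- grid$axes[[2]]$xc
  nx <- length(xc); ny <- length(yc)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("flapflow snapshot t=", format(state$t, digits = 8))
  wl("ASCII")
  wl("DATASET STRUCTURED_GRID")
  wl(sprintf("DIMENSIONS %d %d 1", nx, ny))
  wl(sprintf("POINTS %d float", nx * ny))
  X <- matrix(xc, nx, ny); Y <- matrix(yc, nx, ny, byrow = TRUE)
  writeLines(paste(as.vector(X), as.vector(Y), 0), con)
  wl(sprintf("POINT_DATA %d", nx * ny))
  wl("VECTORS velocity float")
  writeLines(paste(as.vector(state$u), as.vector(state$v), 0), con)
  fields <- c(list(pressure = state$p), extra)
  for (nm in names(fields)) {
    wl(sprintf("SCALARS %s float 1", nm))
    wl("LOOKUP_TABLE default")
    writeLines(format(as.vector(fields[[nm]]), digits = 7), con)
  }
  invisible(file)
}

#' Write tracer particles as a VTK point cloud
#'
#' Legacy POLYDATA with the release-origin tag as a point scalar.
#' @param particles a [particle_set()].
#' @param file output path.
#' @param active_only drop deactivated particles.
#' @export
write_vtk_particles <- function(particles, file, active_only = TRUE) {
  keep <- if (active_only) particles$active else rep(TRUE, nrow(particles$positions))
  p <- particles$positions[keep, , drop = FALSE]
  org <- as.numeric(as.factor(particles$origin))[keep]
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("flapflow particles")
  wl("ASCII")
  wl("DATASET POLYDATA")
  wl(sprintf("POINTS %d float", nrow(p)))
  writeLines(paste(p[, 1], p[, 2], 0), con)
  wl(sprintf("POINT_DATA %d", nrow(p)))
  wl("SCALARS origin float 1")
  wl("LOOKUP_TABLE default")
  writeLines(format(org), con)
  invisible(file)
}

#' Write a triangle mesh as ASCII STL
#' @param mesh a [surface_mesh()] with triangular faces.
#' @param file output path.
#' @param name solid name embedded in the file.
#' @export
write_stl <- function(mesh, file, name = mesh$role) {
  stopifnot(ncol(mesh$faces) == 3L, ncol(mesh$vertices) == 3L)
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-300)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  tri <- function(i) {
    c(sprintf("facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
      "  outer loop",
      sprintf("    vertex %g %g %g", v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
      "  endloop", "endfacet")
  }
  writeLines(unlist(lapply(seq_len(nrow(f)), tri)), con)
  writeLines(paste("endsolid", name), con)
  invisible(file)
}

#' Read an ASCII STL file into a surface mesh
#' @param file path to an ASCII STL.
#' @param role role tag for the resulting mesh.
#' @export
read_stl <- function(file, role = "body") {
  ln <- trimws(readLines(file))
  vx <- ln[startsWith(ln, "vertex")]
  m <- do.call(rbind, lapply(strsplit(vx, "\\s+"), function(s) as.numeric(s[2:4])))
  if (nrow(m) %% 3L != 0L) stop("mesh error: malformed STL (vertex count not multiple of 3)")
  key <- apply(m, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- m[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces, role = role)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a [surface_mesh()].
#' @param file output path.
#' @export
write_obj <- function(mesh, file) {
  con <- file(file, "w")
  on.exit(close(con))
  v <- mesh$vertices
  if (ncol(v) == 2L) v <- cbind(v, 0)
  writeLines(sprintf("v %g %g %g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  if (ncol(f) == 3L) {
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    writeLines(sprintf("l %d %d", f[, 1], f[, 2]), con)
  }
  invisible(file)
}

#' Write a 2D polyline (e.g. planform outline) as CSV
#' @param poly two-column matrix.
#' @param file output path.
#' @export
write_polyline_csv <- function(poly, file) {
  utils::write.csv(data.frame(x = poly[, 1], y = poly[, 2]), file,
                   row.names = FALSE)
  invisible(file)
}

#' Checksum manifest for a run directory
#'
#' MD5 of every file so that a rerun from the same configuration can be
#' verified bit-identical.
#' @param dir run directory.
#' @param file manifest path (default `MANIFEST.md5` inside `dir`).
#' @export
write_manifest <- function(dir, file = file.path(dir, "MANIFEST.md5")) {
  fs <- setdiff(list.files(dir, full.names = TRUE, recursive = TRUE),
                file)
  sums <- tools::md5sum(fs)
  writeLines(sprintf("%s  %s", sums, basename(names(sums))), file)
  invisible(file)
}
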