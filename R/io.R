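# Plain-text exports: legacy ASCII VTK (carries per-vertex and per-triangle
# fields), PLY and OBJ (geometry only), and CSV tables.

#' Write a canvas to a legacy ASCII VTK file
#'
#' Exports the mid-surface mesh with per-vertex fields (thickness, factor
#' levels, polariser) and per-triangle fields (polarity vectors) for external
#' 3D viewers.
#' @param canvas a \code{canvas}.
#' @param path output file path (.vtk).
#' @return invisibly, the path.
#' @export
write_vtk <- function(canvas, path) {
  v <- canvas$vertices
  f <- canvas$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("canvas t=%g h", canvas$time),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  utils::write.table(format(v, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
  scalar <- function(name, x) {
    writeLines(c(sprintf("SCALARS %s float 1", name), "LOOKUP_TABLE default"),
               con)
    writeLines(format(x, digits = 7, trim = TRUE), con)
  }
  scalar("thickness", canvas$thickness)
  for (nm in names(canvas$factors)) scalar(paste0("i_", nm), canvas$factors[[nm]])
  if (!is.null(canvas$pol)) scalar("pol", canvas$pol)
  if (!is.null(canvas$polarity)) {
    writeLines(sprintf("CELL_DATA %d", nrow(f)), con)
    writeLines("VECTORS polarity float", con)
    utils::write.table(format(canvas$polarity, digits = 7, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write canvas geometry as PLY
#' @param canvas a \code{canvas}.
#' @param path output file path (.ply).
#' @return invisibly, the path.
#' @export
write_ply <- function(canvas, path) {
  v <- canvas$vertices
  f <- canvas$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, digits = 9, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write canvas geometry as OBJ
#' @param canvas a \code{canvas}.
#' @param path output file path (.obj).
#' @return invisibly, the path.
#' @export
write_obj <- function(canvas, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(cbind("v", format(canvas$vertices, digits = 9, trim = TRUE)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind("f", canvas$triangles), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a cell layer as CSV
#'
#' One row per cell: id, lineage, clone mark, area, anisotropy, long-axis
#' vector and centroid.
#' @param layer a \code{cell_layer}.
#' @param canvas the bound canvas (NULL for static layers).
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_cells_csv <- function(layer, canvas = NULL, path) {
  m <- cell_shape_metrics(layer, canvas)
  out <- cbind(layer$cells[c("id", "lineage", "clone", "cdiv")],
               m[c("area", "anisotropy", "aspect",
                   "axis_x", "axis_y", "axis_z", "cx", "cy", "cz",
                   "degenerate")])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory: VTK snapshots and a measurement manifest
#'
#' Writes numbered VTK snapshots plus a CSV manifest with time, landmark
#' coordinates and the three section circumference lengths per snapshot.
#' @param traj a \code{trajectory}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the manifest data.frame.
#' @export
write_trajectory <- function(traj, dir, prefix = "snapshot") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (k in seq_along(traj$snapshots)) {
    cv <- traj$snapshots[[k]]
    write_vtk(cv, file.path(dir, sprintf("%s_%03d.vtk", prefix, k)))
    lmpos <- cv$vertices[cv$landmarks, , drop = FALSE]
    circ <- vapply(c("sagittal", "frontal", "transverse"), function(p)
      extract_circumference(cv, p)$length, numeric(1))
    rows[[k]] <- data.frame(snapshot = k, time = cv$time,
                            t(as.vector(t(lmpos))),
                            sagittal = circ[1], frontal = circ[2],
                            transverse = circ[3])
  }
  manifest <- do.call(rbind, rows)
  lmn <- names(traj$snapshots[[1]]$landmarks)
  names(manifest)[3:(2 + 3 * length(lmn))] <-
    paste0(rep(lmn, each = 3), "_", rep(c("x", "y", "z"), length(lmn)))
  utils::write.csv(manifest, file.path(dir, paste0(prefix, "_manifest.csv")),
                   row.names = FALSE)
  invisible(manifest)
}
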