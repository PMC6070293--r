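#' Export and re-import mesh snapshots
#'
#' Writes the mesh cell centers with per-cell scalar fields (always
#' including `area`) as ASCII PLY or legacy-VTK polydata. Values are printed
#' with 17 significant digits so areas and fields round-trip to better than
#' 1e-12 relative. The mesh carries adjacency rather than polygon outlines,
#' so cells are exported as point records ("vertices"), one per Voronoi
#' cell.
#'
#' @param mesh a [build_mesh()] result.
#' @param path output file.
#' @param fields named list of per-cell numeric vectors to attach.
#' @return `path`, invisibly (writers); a list with `points` and `fields`
#'   (readers).
#' @name mesh_io
NULL

fmt17 <- function(x) formatC(x, format = "g", digits = 17)

#' @rdname mesh_io
#' @export
write_mesh_ply <- function(mesh, path, fields = list()) {
  fields <- c(list(area = mesh$area), fields)
  stopifnot(all(vapply(fields, length, 1L) == mesh$n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", mesh$n),
               "property double x", "property double y", "property double z",
               sprintf("property double %s", names(fields)),
               "end_header"), con)
  tab <- cbind(mesh$centroid, do.call(cbind, fields))
  writeLines(apply(tab, 1, function(r) paste(fmt17(r), collapse = " ")), con)
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_mesh_ply <- function(path) {
  lines <- readLines(path)
  end <- which(lines == "end_header")
  props <- sub("^property double ", "", grep("^property double",
                                             lines[seq_len(end)], value = TRUE))
  dat <- read.table(text = lines[-seq_len(end)], col.names = props)
  list(points = as.matrix(dat[, c("x", "y", "z")]),
       fields = as.list(dat[, setdiff(props, c("x", "y", "z")),
                            drop = FALSE]))
}

#' @rdname mesh_io
#' @export
write_mesh_vtk <- function(mesh, path, fields = list()) {
  fields <- c(list(area = mesh$area), fields)
  stopifnot(all(vapply(fields, length, 1L) == mesh$n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ras1zone membrane mesh snapshot", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", mesh$n)), con)
  writeLines(apply(mesh$centroid, 1,
                   function(r) paste(fmt17(r), collapse = " ")), con)
  writeLines(sprintf("VERTICES %d %d", mesh$n, 2 * mesh$n), con)
  writeLines(sprintf("1 %d", seq_len(mesh$n) - 1L), con)
  writeLines(sprintf("POINT_DATA %d", mesh$n), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default", fmt17(fields[[nm]])), con)
  }
  invisible(path)
}

#' @rdname mesh_io
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)
  np <- as.integer(strsplit(lines[ip], " ")[[1]][2])
  pts <- matrix(scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  fields <- list()
  for (is in grep("^SCALARS", lines)) {
    nm <- strsplit(lines[is], " ")[[1]][2]
    fields[[nm]] <- scan(text = lines[(is + 2):(is + 1 + np)], quiet = TRUE)
  }
  list(points = pts, fields = fields)
}
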