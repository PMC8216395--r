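#' Write / read a tissue mesh as JSON
#'
#' A plain JSON dialect of the full simulation state: vertex positions
#' and fixed flags, cell rings, types, per-cell state (age, generation,
#' cycle duration, target areas, polarity), the clock and the registered
#' endo-BC corridors. Lossless round trip.
#'
#' @param mesh a [tissue_mesh()].
#' @param path output file.
#' @return `read_mesh_json` returns the mesh; the writer returns `path`
#'   invisibly.
#' @export
write_mesh_json <- function(mesh, path) {
  x <- list(
    vertices = unname(mesh$pos), fixed = mesh$fixed,
    cells = unname(mesh$cells), type = mesh$type,
    age = mesh$age, generation = mesh$generation,
    cycle_duration = mesh$cycle_duration,
    A0 = mesh$A0, A0_ref = mesh$A0_ref,
    polarity = unname(mesh$polarity), clock = mesh$clock,
    rosettes = mesh$rosettes,
    boundaries = lapply(mesh$boundaries, function(b)
      list(anchor = b$anchor, direction = b$direction,
           half_width = b$half_width, active = b$active)))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cells <- if (is.list(x$cells)) lapply(x$cells, as.integer) else
    lapply(seq_len(nrow(x$cells)), function(i) as.integer(x$cells[i, ]))
  mesh <- tissue_mesh(x$vertices, cells, x$type, fixed = x$fixed,
                      age = x$age, generation = x$generation,
                      cycle_duration = as.numeric(x$cycle_duration),
                      A0 = x$A0, polarity = matrix(x$polarity, ncol = 2),
                      clock = x$clock)
  mesh$A0_ref <- x$A0_ref
  mesh$rosettes <- as.integer(x$rosettes)
  if (length(x$boundaries)) {
    mesh$boundaries <- lapply(seq_len(nrow(x$boundaries)), function(i)
      endo_boundary(unlist(x$boundaries$anchor[i]),
                    unlist(x$boundaries$direction[i]),
                    x$boundaries$half_width[i], x$boundaries$active[i]))
  }
  mesh
}

#' Write a tissue mesh as legacy VTK polydata
#'
#' ASCII VTK file with cells as polygons and per-cell scalars (type code,
#' age, polarity magnitude, and optionally VEGF concentration), viewable
#' in ParaView.
#'
#' @param mesh a [tissue_mesh()].
#' @param path output `.vtk` file.
#' @param field optional `morphogen_field` whose concentration is added
#'   as a per-cell scalar.
#' @return `path` invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, field = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- n_vertices(mesh); nc <- n_cells(mesh)
  writeLines(c("# vtk DataFile Version 3.0",
               paste0("thyromorph snapshot t=", mesh$clock),
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nv, "double")), con)
  writeLines(paste(mesh$pos[, 1], mesh$pos[, 2], 0), con)
  sizes <- lengths(mesh$cells)
  writeLines(paste("POLYGONS", nc, sum(sizes + 1)), con)
  writeLines(vapply(mesh$cells, function(r)
    paste(c(length(r), r - 1L), collapse = " "), character(1)), con)
  writeLines(paste("CELL_DATA", nc), con)
  write_scalar <- function(name, v) {
    writeLines(c(paste("SCALARS", name, "double 1"),
                 "LOOKUP_TABLE default"), con)
    writeLines(as.character(v), con)
  }
  write_scalar("cell_type", type_codes(mesh))
  write_scalar("age", mesh$age)
  write_scalar("polarity_magnitude",
               sqrt(mesh$polarity[, 1]^2 + mesh$polarity[, 2]^2))
  if (!is.null(field)) write_scalar("vegf", field$concentration)
  invisible(path)
}
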