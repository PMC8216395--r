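#' @useDynLib thyromorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
NULL

#' Cell types of the thyroid vertex model
#'
#' The five computational cell types: central and peripheral epithelial
#' cells (thyrocyte progenitors), endothelial tip and stalk cells, and
#' lumen "cells" (follicular cavities represented as a cell type because a
#' vertex model cannot hold stable holes).
#'
#' @format Character vector of length 5.
#' @export
CELL_TYPES <- c("epithelial_central", "epithelial_peripheral",
                "endothelial_tip", "endothelial_stalk", "lumen")

#' Pseudo-type used to key line tension on unshared (tissue-boundary) edges
#' @rdname CELL_TYPES
#' @export
BOUNDARY_TYPE <- "BOUNDARY"

is_epithelial <- function(type) type %in% c("epithelial_central", "epithelial_peripheral")
is_endothelial <- function(type) type %in% c("endothelial_tip", "endothelial_stalk")

#' Construct a tissue mesh
#'
#' The single mutable state object of the vertex model: vertex positions,
#' counter-clockwise polygonal cells with type labels, per-cell state
#' (age, generation, cycle duration, target area, polarity vector), the
#' simulation clock and any registered endothelial boundary corridors.
#'
#' @param pos numeric matrix, one row per vertex, columns x and y, in units
#'   of one nominal cell diameter.
#' @param cells list of integer vectors; each is an ordered vertex ring.
#'   Rings are re-oriented counter-clockwise if supplied clockwise.
#' @param type character vector of cell types (see [CELL_TYPES]).
#' @param fixed logical vector per vertex; fixed vertices are anchored and
#'   never moved by [euler_step()].
#' @param age,generation,cycle_duration,A0 optional per-cell state vectors;
#'   defaults: age 0, generation 0, cycle duration `Inf` (no timed
#'   division), target area equal to current area.
#' @param polarity optional n_cell x 2 matrix of polarity vectors
#'   (defaults to zero).
#' @param clock simulation time in hours.
#' @return An object of class `tissue_mesh`.
#' @export
tissue_mesh <- function(pos, cells, type, fixed = NULL,
                        age = NULL, generation = NULL, cycle_duration = NULL,
                        A0 = NULL, polarity = NULL, clock = 0) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  stopifnot(ncol(pos) == 2, all(is.finite(pos)))
  cells <- lapply(cells, as.integer)
  nc <- length(cells)
  type <- as.character(type)
  stopifnot(length(type) == nc, all(type %in% CELL_TYPES))
  mesh <- structure(list(
    pos = pos,
    fixed = if (is.null(fixed)) rep(FALSE, nrow(pos)) else as.logical(fixed),
    cells = cells,
    type = type,
    age = if (is.null(age)) rep(0, nc) else as.numeric(age),
    generation = if (is.null(generation)) rep(0L, nc) else as.integer(generation),
    cycle_duration = if (is.null(cycle_duration)) rep(Inf, nc) else as.numeric(cycle_duration),
    A0 = NULL,
    polarity = if (is.null(polarity)) matrix(0, nc, 2) else as.matrix(polarity),
    clock = clock,
    boundaries = list(),
    rosettes = integer(0),
    split_cooldown = matrix(0, 0, 3),
    next_cell_id = nc + 1L
  ), class = "tissue_mesh")
  # orient all rings CCW
  for (i in seq_len(nc)) {
    if (ring_signed_area(pos, cells[[i]]) < 0)
      mesh$cells[[i]] <- rev(mesh$cells[[i]])
  }
  mesh$A0 <- if (is.null(A0)) cell_areas(mesh) else as.numeric(A0)
  # mature target area: what the instantaneous target relaxes toward as the
  # cell ages through its cycle (equal to A0 at construction)
  mesh$A0_ref <- mesh$A0
  mesh
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat("<tissue_mesh> t =", format(x$clock, digits = 4), "h;",
      nrow(x$pos), "vertices,", length(x$cells), "cells\n")
  print(table(factor(x$type, levels = CELL_TYPES)))
  invisible(x)
}

n_cells <- function(mesh) length(mesh$cells)
n_vertices <- function(mesh) nrow(mesh$pos)

ring_signed_area <- function(pos, ring) {
  x <- pos[ring, 1]; y <- pos[ring, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Cell area by the shoelace formula
#'
#' @param mesh a [tissue_mesh()].
#' @param cell cell index (single integer).
#' @return Strictly positive area for a valid CCW simple polygon.
#' @export
cell_area <- function(mesh, cell) {
  ring <- mesh$cells[[cell]]
  if (length(unique(ring)) < 3)
    stop("degenerate polygon in cell ", cell, ": mesh is corrupt")
  ring_signed_area(mesh$pos, ring)
}

#' Areas, perimeters and centroids of all cells
#'
#' Vectorised geometric measures over the whole mesh. Centroids are the
#' polygon area centroids (not vertex means).
#'
#' @param mesh a [tissue_mesh()].
#' @return numeric vector (areas, perimeters) or n x 2 matrix (centroids).
#' @export
cell_areas <- function(mesh) {
  he <- half_edges(mesh)
  p <- mesh$pos
  cr <- p[he$from, 1] * p[he$to, 2] - p[he$to, 1] * p[he$from, 2]
  0.5 * as.numeric(rowsum(cr, he$cell))
}

#' @rdname cell_areas
#' @export
cell_perimeters <- function(mesh) {
  he <- half_edges(mesh)
  d <- mesh$pos[he$to, , drop = FALSE] - mesh$pos[he$from, , drop = FALSE]
  as.numeric(rowsum(sqrt(d[, 1]^2 + d[, 2]^2), he$cell))
}

#' @rdname cell_areas
#' @export
cell_centroids <- function(mesh) {
  he <- half_edges(mesh)
  p <- mesh$pos
  cr <- p[he$from, 1] * p[he$to, 2] - p[he$to, 1] * p[he$from, 2]
  a6 <- 6 * 0.5 * as.numeric(rowsum(cr, he$cell))
  cx <- rowsum((p[he$from, 1] + p[he$to, 1]) * cr, he$cell) / a6
  cy <- rowsum((p[he$from, 2] + p[he$to, 2]) * cr, he$cell) / a6
  cbind(as.numeric(cx), as.numeric(cy))
}

# Directed half-edges: one per (cell, consecutive vertex pair).
half_edges <- function(mesh) {
  rings <- mesh$cells
  lens <- lengths(rings)
  from <- unlist(rings, use.names = FALSE)
  to <- unlist(lapply(rings, function(r) c(r[-1], r[1])), use.names = FALSE)
  list(cell = rep.int(seq_along(rings), lens), from = from, to = to)
}

edge_key <- function(a, b) {
  pmin(a, b) * 2^26 + pmax(a, b)
}

# Plain-list core of mesh_edges() (hot path; no tibble overhead).
edge_struct <- function(mesh) {
  he <- half_edges(mesh)
  k <- edge_key(he$from, he$to)
  o <- order(k)
  k <- k[o]; cell <- he$cell[o]; from <- he$from[o]; to <- he$to[o]
  first <- !duplicated(k)
  idx1 <- which(first)
  # map each edge to its 1 or 2 half-edges
  grp <- cumsum(first)
  cnt <- tabulate(grp)
  if (any(cnt > 2))
    stop("edge shared by more than two cells: mesh is corrupt")
  cell2 <- rep(NA_integer_, length(idx1))
  second <- which(!first)
  cell2[grp[second]] <- cell[second]
  v1 <- pmin(from[idx1], to[idx1]); v2 <- pmax(from[idx1], to[idx1])
  len <- sqrt((mesh$pos[v1, 1] - mesh$pos[v2, 1])^2 +
                (mesh$pos[v1, 2] - mesh$pos[v2, 2])^2)
  list(v1 = v1, v2 = v2, cell1 = cell[idx1], cell2 = cell2,
       length = len, boundary = is.na(cell2))
}

#' Undirected edge table of the mesh
#'
#' Each row is one plasma-membrane segment: its vertex pair, the one or two
#' adjacent cells, its length and whether it lies on the tissue boundary.
#'
#' @param mesh a [tissue_mesh()].
#' @return A tibble with columns `v1`, `v2`, `cell1`, `cell2` (NA on the
#'   tissue boundary), `length`, `boundary`.
#' @export
mesh_edges <- function(mesh) {
  tibble::as_tibble(edge_struct(mesh))
}

#' Which vertices lie on the tissue boundary?
#'
#' A vertex is a boundary vertex iff it belongs to at least one unshared
#' (single-cell) edge.
#'
#' @param mesh a [tissue_mesh()].
#' @return logical vector over vertices.
#' @export
boundary_vertices <- function(mesh) {
  he <- half_edges(mesh)
  k <- edge_key(he$from, he$to)
  dup <- duplicated(k) | duplicated(k, fromLast = TRUE)
  out <- rep(FALSE, n_vertices(mesh))
  out[he$from[!dup]] <- TRUE
  out[he$to[!dup]] <- TRUE
  out
}

# Number of cells sharing each vertex.
vertex_cell_degree <- function(mesh) {
  tabulate(unlist(mesh$cells, use.names = FALSE), nbins = n_vertices(mesh))
}

# Cells incident to each vertex (list).
vertex_cells <- function(mesh) {
  he <- unlist(mesh$cells, use.names = FALSE)
  cid <- rep.int(seq_along(mesh$cells), lengths(mesh$cells))
  split(cid, factor(he, levels = seq_len(n_vertices(mesh))))
}

#' Cell adjacency pairs
#'
#' Unordered pairs of cells sharing at least one edge, with the total
#' shared edge length (used as finite-volume weights by the morphogen
#' solver).
#'
#' @param mesh a [tissue_mesh()].
#' @return tibble with columns `a`, `b` (a < b), `shared_length`.
#' @export
cell_adjacency <- function(mesh) {
  tibble::as_tibble(adj_struct(mesh))
}

# Plain-list core of cell_adjacency().
adj_struct <- function(mesh, ed = edge_struct(mesh)) {
  keep <- !ed$boundary
  if (!any(keep))
    return(list(a = integer(0), b = integer(0), shared_length = numeric(0)))
  c1 <- ed$cell1[keep]; c2 <- ed$cell2[keep]; len <- ed$length[keep]
  a <- pmin(c1, c2); b <- pmax(c1, c2)
  k <- a * 2^26 + b
  agg <- rowsum(len, k)
  kk <- as.numeric(rownames(agg))
  list(a = as.integer(kk %/% 2^26), b = as.integer(kk %% 2^26),
       shared_length = as.numeric(agg))
}

segments_intersect <- function(p1, p2, q1, q2) {
  d1 <- (p2[1] - p1[1]) * (q1[2] - p1[2]) - (p2[2] - p1[2]) * (q1[1] - p1[1])
  d2 <- (p2[1] - p1[1]) * (q2[2] - p1[2]) - (p2[2] - p1[2]) * (q2[1] - p1[1])
  d3 <- (q2[1] - q1[1]) * (p1[2] - q1[2]) - (q2[2] - q1[2]) * (p1[1] - q1[1])
  d4 <- (q2[1] - q1[1]) * (p2[2] - q1[2]) - (q2[2] - q1[2]) * (p2[1] - q1[1])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# Simple-polygon check: no pair of non-adjacent edges intersects (O(n^2),
# compiled).
ring_is_simple <- function(pos, ring) {
  ring_simple_cpp(pos, as.integer(ring))
}

#' Check the structural invariants of a tissue mesh
#'
#' Verifies the topological and geometric contract all dynamics rely on:
#' rings of at least three distinct vertices with positive signed area,
#' interior vertices shared by exactly three cells (tracked rosettes
#' excepted), boundary vertices by one or two, no edge shared by more than
#' two cells, no self-intersecting cell, finite positions.
#'
#' @param mesh a [tissue_mesh()].
#' @param check_simple also run the O(n^2) per-cell self-intersection test
#'   (slower; on by default).
#' @return `TRUE` invisibly, or stops with a description of the violation.
#' @export
mesh_check <- function(mesh, check_simple = TRUE) {
  if (!all(is.finite(mesh$pos))) stop("non-finite vertex positions")
  nv <- n_vertices(mesh)
  for (i in seq_along(mesh$cells)) {
    ring <- mesh$cells[[i]]
    if (length(ring) < 3) stop("cell ", i, " has fewer than 3 vertices")
    if (anyDuplicated(ring)) stop("cell ", i, " has a repeated vertex")
    if (any(ring < 1 | ring > nv)) stop("cell ", i, " references a missing vertex")
    if (ring_signed_area(mesh$pos, ring) <= 0)
      stop("cell ", i, " is not counter-clockwise / has non-positive area")
    if (check_simple && !ring_is_simple(mesh$pos, ring))
      stop("cell ", i, " is self-intersecting")
  }
  deg <- vertex_cell_degree(mesh)
  used <- deg > 0
  bnd <- boundary_vertices(mesh)
  bad_int <- which(used & !bnd & deg != 3)
  bad_int <- setdiff(bad_int, mesh$rosettes)
  if (length(bad_int))
    stop("interior vertex ", bad_int[1], " shared by ", deg[bad_int[1]],
         " cells (expected 3)")
  bad_bnd <- which(used & bnd & (deg < 1 | deg > 2))
  bad_bnd <- setdiff(bad_bnd, mesh$rosettes)
  if (length(bad_bnd))
    stop("boundary vertex ", bad_bnd[1], " shared by ", deg[bad_bnd[1]],
         " cells (expected 1-2)")
  ed <- mesh_edges(mesh)  # errors if an edge has >2 cells
  if (any(ed$length == 0)) stop("zero-length edge present")
  invisible(TRUE)
}

# Drop vertices not referenced by any cell, remapping rings; keeps
# per-vertex attributes in step.
compact_vertices <- function(mesh) {
  used <- sort(unique(unlist(mesh$cells, use.names = FALSE)))
  if (length(used) == n_vertices(mesh)) return(mesh)
  map <- integer(n_vertices(mesh))
  map[used] <- seq_along(used)
  mesh$pos <- mesh$pos[used, , drop = FALSE]
  mesh$fixed <- mesh$fixed[used]
  mesh$cells <- lapply(mesh$cells, function(r) map[r])
  if (length(mesh$rosettes)) {
    ros <- map[mesh$rosettes]
    mesh$rosettes <- ros[ros > 0]
  }
  mesh
}

# Remove cells by index, keeping per-cell state aligned.
drop_cells <- function(mesh, idx) {
  if (!length(idx)) return(mesh)
  keep <- setdiff(seq_along(mesh$cells), idx)
  mesh$cells <- mesh$cells[keep]
  mesh$type <- mesh$type[keep]
  mesh$age <- mesh$age[keep]
  mesh$generation <- mesh$generation[keep]
  mesh$cycle_duration <- mesh$cycle_duration[keep]
  mesh$A0 <- mesh$A0[keep]
  mesh$A0_ref <- mesh$A0_ref[keep]
  mesh$polarity <- mesh$polarity[keep, , drop = FALSE]
  mesh
}

# Append one cell with state; returns list(mesh, id).
append_cell <- function(mesh, ring, type, age = 0, generation = 0L,
                        cycle_duration = Inf, A0 = NULL, A0_ref = NULL,
                        polarity = c(0, 0)) {
  mesh$cells[[length(mesh$cells) + 1L]] <- as.integer(ring)
  mesh$type <- c(mesh$type, type)
  mesh$age <- c(mesh$age, age)
  mesh$generation <- c(mesh$generation, as.integer(generation))
  mesh$cycle_duration <- c(mesh$cycle_duration, cycle_duration)
  id <- length(mesh$cells)
  mesh$A0 <- c(mesh$A0, if (is.null(A0)) cell_area(mesh, id) else A0)
  mesh$A0_ref <- c(mesh$A0_ref, if (is.null(A0_ref)) mesh$A0[id] else A0_ref)
  mesh$polarity <- rbind(mesh$polarity, matrix(polarity, 1, 2))
  list(mesh = mesh, id = id)
}

# Append vertices; returns list(mesh, ids).
append_vertices <- function(mesh, xy, fixed = FALSE) {
  xy <- matrix(xy, ncol = 2)
  n0 <- n_vertices(mesh)
  mesh$pos <- rbind(mesh$pos, xy)
  mesh$fixed <- c(mesh$fixed, rep(fixed, length.out = nrow(xy)))
  list(mesh = mesh, ids = n0 + seq_len(nrow(xy)))
}
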