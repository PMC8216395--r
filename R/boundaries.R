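#' Endothelial boundary corridor (endo-BC)
#'
#' Two parallel semi-infinite rays starting beside the original position
#' of a founding stalk cell and extending outward, standing in for the
#' distant parent vessel the 2D section cannot show. Epithelial vertices
#' may not enter the corridor between the rays, which prevents separated
#' epithelial buds from fusing over a nascent vessel.
#'
#' @param anchor 2D point: original stalk centroid.
#' @param direction outward unit vector.
#' @param half_width corridor half-width (length units, >= 0).
#' @param active logical.
#' @return list of class `endo_boundary`.
#' @export
endo_boundary <- function(anchor, direction, half_width, active = TRUE) {
  nrm <- sqrt(sum(direction^2))
  stopifnot(nrm > 0, half_width >= 0)
  structure(list(anchor = as.numeric(anchor),
                 direction = as.numeric(direction) / nrm,
                 half_width = half_width, active = active),
            class = "endo_boundary")
}

# Which cells contain each vertex, as type-membership flags.
vertex_touches <- function(mesh, types) {
  out <- rep(FALSE, n_vertices(mesh))
  sel <- which(mesh$type %in% types)
  if (length(sel))
    out[unique(unlist(mesh$cells[sel], use.names = FALSE))] <- TRUE
  out
}

#' Register an endothelial boundary for a peripheral stalk cell
#'
#' Creates the corridor anchored at the stalk centroid, directed along the
#' outward normal of the local tissue boundary, with half-width equal to
#' half the stalk's boundary-edge span; the stalk's outermost boundary
#' vertices are fixed (they represent the connection to a distant vessel
#' and must not drift).
#'
#' @param mesh a [tissue_mesh()].
#' @param stalk_cell index of a stalk cell touching the tissue boundary.
#' @return The mesh, with the new corridor appended to `mesh$boundaries`
#'   and the anchoring vertices fixed.
#' @export
register_endo_boundary <- function(mesh, stalk_cell) {
  ring <- mesh$cells[[stalk_cell]]
  ed <- edge_struct(mesh)
  bi <- which(ed$boundary & ed$cell1 == stalk_cell)
  bed <- list(v1 = ed$v1[bi], v2 = ed$v2[bi])
  if (!length(bi)) stop("stalk cell ", stalk_cell, " does not touch the tissue boundary")
  # outward normal of the cell's boundary edges (interior on the left of
  # each CCW half-edge), length-weighted
  n_acc <- c(0, 0)
  nring <- length(ring)
  for (i in seq_len(nring)) {
    a <- ring[i]; b <- ring[i %% nring + 1L]
    if (any((bed$v1 == min(a, b)) & (bed$v2 == max(a, b)))) {
      d <- mesh$pos[b, ] - mesh$pos[a, ]
      n_acc <- n_acc + c(d[2], -d[1])
    }
  }
  nrm <- sqrt(sum(n_acc^2))
  if (nrm == 0) stop("degenerate boundary normal for stalk cell ", stalk_cell)
  u <- n_acc / nrm
  anchor <- ring_centroid(mesh$pos, ring)
  nn <- c(-u[2], u[1])
  bv <- unique(c(bed$v1, bed$v2))
  s <- as.numeric((mesh$pos[bv, , drop = FALSE] -
                     matrix(anchor, length(bv), 2, byrow = TRUE)) %*% nn)
  half_width <- (max(s) - min(s)) / 2
  # fix the outermost boundary vertices (largest projection along u)
  t_proj <- as.numeric((mesh$pos[bv, , drop = FALSE] -
                          matrix(anchor, length(bv), 2, byrow = TRUE)) %*% u)
  outer <- bv[order(-t_proj)][seq_len(min(2L, length(bv)))]
  mesh$fixed[outer] <- TRUE
  mesh$boundaries[[length(mesh$boundaries) + 1L]] <-
    endo_boundary(anchor, u, half_width)
  mesh
}

#' Relocate epithelial vertices out of endo-BC corridors
#'
#' Every vertex belonging only to epithelial cells that lies strictly
#' inside an active corridor (outward of the anchor, between the two
#' rays) is projected to the nearest point on the nearer ray. Applied
#' after every Euler step. Endothelial and lumen vertices are unaffected
#' (the vessel itself lives in the corridor). Idempotent.
#'
#' @param mesh a [tissue_mesh()].
#' @param boundaries list of [endo_boundary()] objects (default: the
#'   corridors registered on the mesh).
#' @return The mesh with relocated vertices.
#' @export
enforce_corridors <- function(mesh, boundaries = mesh$boundaries) {
  if (!length(boundaries)) return(mesh)
  epi_only <- vertex_touches(mesh, c("epithelial_central", "epithelial_peripheral")) &
    !vertex_touches(mesh, c("endothelial_tip", "endothelial_stalk", "lumen"))
  epi_only <- epi_only & !mesh$fixed
  if (!any(epi_only)) return(mesh)
  idx <- which(epi_only)
  P <- mesh$pos[idx, , drop = FALSE]
  # tie-break side by the centroid of (one of) the vertex's cells
  vc <- vertex_cells(mesh)
  for (bc in boundaries) {
    if (!bc$active) next
    u <- bc$direction; nn <- c(-u[2], u[1])
    rel <- P - matrix(bc$anchor, nrow(P), 2, byrow = TRUE)
    t <- rel %*% u
    s <- rel %*% nn
    inside <- (t > 0) & (abs(s) < bc$half_width)
    if (!any(inside)) next
    for (k in which(inside)) {
      side <- sign(s[k])
      if (side == 0) {
        cc <- ring_centroid(mesh$pos, mesh$cells[[vc[[idx[k]]][1]]])
        side <- sign(sum((cc - bc$anchor) * nn))
        if (side == 0) side <- 1
      }
      P[k, ] <- P[k, ] + (side * bc$half_width - s[k]) * nn
    }
  }
  mesh$pos[idx, ] <- P
  mesh
}
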