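# Second moments of area of a polygon about its centroid (Sxx, Syy, Sxy).
polygon_second_moments <- function(pos, ring) {
  x <- pos[ring, 1]; y <- pos[ring, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- 0.5 * sum(cr)
  if (abs(A) < .Machine$double.eps) stop("degenerate (zero-area) cell")
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  Sxx <- sum((x^2 + x * xn + xn^2) * cr) / 12 - A * cx^2
  Syy <- sum((y^2 + y * yn + yn^2) * cr) / 12 - A * cy^2
  Sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24 - A * cx * cy
  list(A = A, centroid = c(cx, cy), M = matrix(c(Sxx, Sxy, Sxy, Syy), 2, 2))
}

#' Elongation factor of a cell
#'
#' The square root of the ratio of the principal second moments of area of
#' the cell polygon: 1 for shapes with three-fold or higher symmetry,
#' larger for stretched cells. Drives shape-triggered stalk-cell division.
#'
#' @param mesh a [tissue_mesh()].
#' @param cell cell index.
#' @return Scalar `>= 1`.
#' @export
elongation_factor <- function(mesh, cell) {
  sm <- polygon_second_moments(mesh$pos, mesh$cells[[cell]])
  ev <- eigen(sm$M, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) stop("degenerate cell shape")
  sqrt(ev[1] / ev[2])
}

# Division axis: direction of the line (unit vector) through the centroid.
# Default is the shortest axis = minor principal axis of the second-moment
# tensor; near-ties break to the +x direction.
shortest_axis <- function(mesh, cell) {
  sm <- polygon_second_moments(mesh$pos, mesh$cells[[cell]])
  eg <- eigen(sm$M, symmetric = TRUE)
  if (abs(eg$values[1] - eg$values[2]) < 1e-9 * sum(abs(eg$values)))
    return(c(1, 0))
  u <- eg$vectors[, 2]   # eigenvector of the smaller principal moment
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  u
}

# Intersections of the line centroid + t*u with the ring's edges.
# Returns NULL unless the line crosses exactly two edges.
ring_line_cuts <- function(pos, ring, centre, u) {
  n <- length(ring)
  pts <- pos[ring, , drop = FALSE]
  s <- u[1] * (pts[, 2] - centre[2]) - u[2] * (pts[, 1] - centre[1])
  if (any(abs(s) < 1e-12)) return(NULL)          # vertex on line: caller perturbs
  sn <- c(s[-1], s[1])
  cross_idx <- which(s * sn < 0)
  if (length(cross_idx) != 2) return(NULL)
  cuts <- lapply(cross_idx, function(i) {
    j <- i %% n + 1L
    t <- s[i] / (s[i] - s[j])
    list(i = i, point = pts[i, ] + t * (pts[j, ] - pts[i, ]))
  })
  cuts
}

#' Divide a cell along an axis through its centroid
#'
#' Splits the mother cell by a straight line through its area centroid;
#' the default axis is the cell's shortest axis (minor principal axis of
#' its second moments), the standard division rule for vertex models. Two
#' new vertices are created where the line crosses the mother's edges and
#' are also inserted into the neighbouring cells' rings, keeping every
#' interior vertex at cell-degree three. The daughters' areas sum exactly
#' to the mother's; each daughter's target area is half the mother's.
#' Daughter one replaces the mother in place, daughter two is appended;
#' both inherit the mother's type and state (callers reset ages and
#' generations for cycle-driven divisions).
#'
#' @param mesh a [tissue_mesh()].
#' @param cell index of the mother cell.
#' @param axis optional unit vector giving the division-line direction;
#'   default [the shortest axis].
#' @return `list(mesh = updated mesh, daughters = c(id1, id2))`.
#' @export
divide_cell <- function(mesh, cell, axis = NULL) {
  ring <- mesh$cells[[cell]]
  if (length(ring) < 3) stop("cannot divide a degenerate cell")
  sm <- polygon_second_moments(mesh$pos, mesh$cells[[cell]])
  u <- if (is.null(axis)) shortest_axis(mesh, cell) else axis / sqrt(sum(axis^2))
  cuts <- NULL
  for (k in 0:8) {                                # perturb axis on degeneracy
    th <- k * 1.7e-5
    ru <- c(cos(th) * u[1] - sin(th) * u[2], sin(th) * u[1] + cos(th) * u[2])
    cuts <- ring_line_cuts(mesh$pos, ring, sm$centroid, ru)
    if (!is.null(cuts)) break
  }
  if (is.null(cuts))
    stop("division line fails to cross exactly two edges of cell ", cell)

  res <- append_vertices(mesh, rbind(cuts[[1]]$point, cuts[[2]]$point))
  mesh <- res$mesh
  w1 <- res$ids[1]; w2 <- res$ids[2]
  n <- length(ring)
  i1 <- cuts[[1]]$i; i2 <- cuts[[2]]$i            # cut edges (i, i+1), i1 < i2
  # daughter rings (both CCW): w1, ring[i1+1..i2], w2 | w2, ring[i2+1..i1], w1
  seq_a <- ring[(i1 + 1):i2]
  seq_b <- ring[c(if (i2 < n) (i2 + 1):n else integer(0), 1:i1)]
  ring1 <- c(w1, seq_a, w2)
  ring2 <- c(w2, seq_b, w1)

  # insert cut vertices into the neighbours sharing the cut edges
  for (ci in 1:2) {
    cut <- cuts[[ci]]
    va <- ring[cut$i]; vb <- ring[cut$i %% n + 1L]
    w <- if (ci == 1) w1 else w2
    for (j in seq_along(mesh$cells)) {
      if (j == cell) next
      r <- mesh$cells[[j]]
      nn <- length(r)
      for (ii in seq_len(nn)) {
        jj <- ii %% nn + 1L
        if ((r[ii] == vb && r[jj] == va)) {       # neighbour's half-edge
          mesh$cells[[j]] <- append(r, w, after = ii)
          break
        }
      }
    }
  }

  mesh$cells[[cell]] <- ring1
  half_A0 <- mesh$A0[cell] / 2
  mesh$A0[cell] <- half_A0
  res2 <- append_cell(mesh, ring2, mesh$type[cell],
                      age = mesh$age[cell], generation = mesh$generation[cell],
                      cycle_duration = mesh$cycle_duration[cell],
                      A0 = half_A0, A0_ref = mesh$A0_ref[cell],
                      polarity = mesh$polarity[cell, ])
  mesh <- res2$mesh
  edge_struct(mesh)   # errors when the surgery corrupted edge sharing
  list(mesh = track_violations(mesh), daughters = c(cell, res2$id))
}
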