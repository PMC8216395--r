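#' Energy parameters of the vertex model
#'
#' Holds the mechanical parameters of the tissue energy
#' \deqn{E = \sum_\alpha \frac{K}{2}(A_\alpha - A_0)^2
#'       + \sum_j \Lambda_j L_j + \sum_\alpha \frac{\Gamma}{2} P_\alpha^2,}
#' with area elasticity \eqn{K} and perimeter contractility \eqn{\Gamma}
#' per cell type, and line tension \eqn{\Lambda} per unordered pair of the
#' two cell types flanking an edge (tissue-boundary edges are keyed
#' against the pseudo-type `"BOUNDARY"`). Differential adhesion is encoded
#' entirely in the \eqn{\Lambda} table: lower (more negative) values mean
#' stronger adhesion along that interface.
#'
#' @param K named numeric vector of area elasticities, one per cell type
#'   (names from [CELL_TYPES]); a scalar is recycled.
#' @param gamma perimeter contractility per type; scalar recycled.
#' @param lambda symmetric numeric matrix with dimnames
#'   `c(CELL_TYPES, "BOUNDARY")`, or a scalar used for every pair.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(K = 1, gamma = 0.04, lambda = 0.12) {
  all_t <- c(CELL_TYPES, BOUNDARY_TYPE)
  if (length(K) == 1) K <- stats::setNames(rep(K, 5), CELL_TYPES)
  if (length(gamma) == 1) gamma <- stats::setNames(rep(gamma, 5), CELL_TYPES)
  stopifnot(all(CELL_TYPES %in% names(K)), all(CELL_TYPES %in% names(gamma)),
            all(K >= 0), all(gamma >= 0))
  if (is.matrix(lambda)) {
    stopifnot(identical(rownames(lambda), all_t), identical(colnames(lambda), all_t))
    if (max(abs(lambda - t(lambda))) > 1e-12) stop("lambda matrix must be symmetric")
  } else {
    stopifnot(length(lambda) == 1)
    lambda <- matrix(lambda, 6, 6, dimnames = list(all_t, all_t))
  }
  structure(list(K = K[CELL_TYPES], gamma = gamma[CELL_TYPES], lambda = lambda),
            class = "energy_params")
}

#' Set one line-tension entry symmetrically
#'
#' @param params an [energy_params()] object.
#' @param a,b cell types (or `"BOUNDARY"`).
#' @param value new line tension for the `a`--`b` interface.
#' @return The modified `energy_params`.
#' @export
set_lambda <- function(params, a, b, value) {
  stopifnot(a %in% rownames(params$lambda), b %in% rownames(params$lambda))
  params$lambda[a, b] <- value
  params$lambda[b, a] <- value
  params
}

# Lambda per edge row of mesh_edges() output.
edge_lambda <- function(mesh, params, edges) {
  t1 <- mesh$type[edges$cell1]
  t2 <- ifelse(is.na(edges$cell2), BOUNDARY_TYPE, mesh$type[edges$cell2])
  lam <- params$lambda[cbind(t1, t2)]
  if (anyNA(lam)) stop("missing line-tension entry for a type pair")
  lam
}

#' Total tissue energy
#'
#' Evaluates the tissue energy (area elasticity + line tension +
#' perimeter contractility), with every undirected edge counted once.
#'
#' @param mesh a [tissue_mesh()].
#' @param params an [energy_params()].
#' @return Scalar energy.
#' @export
total_energy <- function(mesh, params) {
  A <- cell_areas(mesh)
  P <- cell_perimeters(mesh)
  K <- params$K[mesh$type]
  G <- params$gamma[mesh$type]
  ed <- edge_struct(mesh)
  lam <- edge_lambda(mesh, params, ed)
  sum(K / 2 * (A - mesh$A0)^2) + sum(lam * ed$length) + sum(G / 2 * P^2)
}

#' Forces on every vertex
#'
#' The negative gradient of [total_energy()] with respect to each vertex
#' position: per incident cell, an area-elastic term
#' \eqn{-K(A-A_0)\nabla A} and a contractility term \eqn{-\Gamma P \nabla P};
#' per incident edge, a tension term \eqn{-\Lambda \nabla L}. Forces are
#' computed for fixed vertices too; [euler_step()] masks them.
#'
#' @param mesh a [tissue_mesh()].
#' @param params an [energy_params()].
#' @return n_vertices x 2 matrix of forces.
#' @export
vertex_forces <- function(mesh, params) {
  p <- mesh$pos
  rings <- mesh$cells
  lens <- lengths(rings)
  v <- unlist(rings, use.names = FALSE)
  nxt <- unlist(lapply(rings, function(r) c(r[-1], r[1])), use.names = FALSE)
  prv <- unlist(lapply(rings, function(r) c(r[length(r)], r[-length(r)])), use.names = FALSE)
  cid <- rep.int(seq_along(rings), lens)

  A <- cell_areas(mesh); P <- cell_perimeters(mesh)
  K <- params$K[mesh$type]; G <- params$gamma[mesh$type]

  # dA/dv = 0.5 * (y_next - y_prev, x_prev - x_next) for CCW rings
  dAx <- 0.5 * (p[nxt, 2] - p[prv, 2])
  dAy <- 0.5 * (p[prv, 1] - p[nxt, 1])
  # dP/dv = unit(v - prev) + unit(v - next)
  d1 <- p[v, , drop = FALSE] - p[prv, , drop = FALSE]
  d2 <- p[v, , drop = FALSE] - p[nxt, , drop = FALSE]
  l1 <- sqrt(d1[, 1]^2 + d1[, 2]^2); l2 <- sqrt(d2[, 1]^2 + d2[, 2]^2)
  l1[l1 == 0] <- 1; l2[l2 == 0] <- 1
  dPx <- d1[, 1] / l1 + d2[, 1] / l2
  dPy <- d1[, 2] / l1 + d2[, 2] / l2

  ka <- -K[cid] * (A[cid] - mesh$A0[cid])
  gp <- -G[cid] * P[cid]
  fx <- ka * dAx + gp * dPx
  fy <- ka * dAy + gp * dPy

  F <- matrix(0, n_vertices(mesh), 2)
  sx <- rowsum(fx, v); sy <- rowsum(fy, v)
  iv <- as.integer(rownames(sx))
  F[iv, 1] <- F[iv, 1] + sx
  F[iv, 2] <- F[iv, 2] + sy

  ed <- edge_struct(mesh)
  lam <- edge_lambda(mesh, params, ed)
  dv <- p[ed$v1, , drop = FALSE] - p[ed$v2, , drop = FALSE]
  L <- ed$length; L[L == 0] <- 1
  tx <- -lam * dv[, 1] / L; ty <- -lam * dv[, 2] / L
  ex <- rowsum(c(tx, -tx), c(ed$v1, ed$v2)); ey <- rowsum(c(ty, -ty), c(ed$v1, ed$v2))
  ie <- as.integer(rownames(ex))
  F[ie, 1] <- F[ie, 1] + ex
  F[ie, 2] <- F[ie, 2] + ey
  F
}

#' Forward-Euler step of the equation of motion
#'
#' Overdamped dynamics with unit mobility: every non-fixed vertex moves by
#' `force * dt`; fixed vertices (endothelial anchors) do not move. The
#' simulation clock advances by `dt`.
#'
#' @param mesh a [tissue_mesh()].
#' @param forces n_vertices x 2 matrix, e.g. from [vertex_forces()] plus
#'   any motile forces.
#' @param dt time step in hours (default 0.001).
#' @return The updated mesh.
#' @export
euler_step <- function(mesh, forces, dt = 0.001) {
  stopifnot(dt > 0)
  if (!all(is.finite(forces)))
    stop("non-finite force encountered: numerical instability at t = ", mesh$clock)
  mov <- !mesh$fixed
  mesh$pos[mov, ] <- mesh$pos[mov, , drop = FALSE] + dt * forces[mov, , drop = FALSE]
  mesh$clock <- mesh$clock + dt
  mesh
}
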