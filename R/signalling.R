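#' VEGF morphogen parameters
#'
#' Reaction-diffusion parameters of the epithelium-produced VEGF field:
#' every epithelial cell is a source of strength `s`, the field diffuses
#' with coefficient `D` over the tissue and degrades at rate `k_deg`,
#' with the concentration clamped to zero on the tissue boundary. Setting
#' `s = 0` is the in-silico VEGFA knockout.
#'
#' @param D diffusion coefficient (length^2/h).
#' @param s production rate per epithelial cell (conc/h).
#' @param k_deg degradation rate (1/h).
#' @return list of class `morphogen_params`.
#' @export
morphogen_params <- function(D = 1, s = 1, k_deg = 1) {
  stopifnot(D > 0, k_deg > 0, s >= 0)
  structure(list(D = D, s = s, k_deg = k_deg, boundary_value = 0),
            class = "morphogen_params")
}

#' Chemotaxis parameters for endothelial tip cells
#'
#' @param mu motile-force magnitude applied to every vertex of a tip cell
#'   along the local VEGF gradient direction.
#' @param gradient_floor minimum gradient magnitude below which tips idle.
#' @return list of class `chemotaxis_params`.
#' @export
chemotaxis_params <- function(mu = 0.5, gradient_floor = 1e-6) {
  stopifnot(mu >= 0, gradient_floor >= 0)
  structure(list(mu = mu, gradient_floor = gradient_floor),
            class = "chemotaxis_params")
}

#' Solve the steady-state VEGF field on the cell-adjacency graph
#'
#' Finite-volume discretisation on the dual of the cell adjacency: flux
#' between adjacent cells is weighted by shared-edge length over
#' centre-to-centre distance, sources live on epithelial cells, and the
#' concentration is held at zero (Dirichlet) on tissue-boundary cells.
#' Solves \eqn{0 = D \nabla^2 c + s\,1_{epithelial} - k c} quasi-statically
#' (diffusion assumed fast relative to vertex motion). Disconnected
#' components are handled naturally by the sparse solve.
#'
#' @param mesh a [tissue_mesh()] with at least one cell.
#' @param params a [morphogen_params()].
#' @param dirichlet integer cell indices clamped to zero; defaults to all
#'   cells touching the tissue boundary.
#' @param gradient also evaluate the per-cell gradient (default TRUE; the
#'   simulation loop evaluates gradients only at tip cells instead).
#' @return list of class `morphogen_field`: `concentration` (per cell,
#'   nonnegative) and `gradient` (n_cell x 2, from [vegf_gradient()], or
#'   NULL).
#' @export
solve_vegf_field <- function(mesh, params, dirichlet = NULL, gradient = TRUE) {
  nc <- n_cells(mesh)
  stopifnot(nc >= 1)
  ed <- edge_struct(mesh)
  if (is.null(dirichlet)) dirichlet <- unique(ed$cell1[ed$boundary])
  conc <- solve_vegf_core(adj_struct(mesh, ed), cell_centroids(mesh),
                          cell_areas(mesh), is_epithelial(mesh$type),
                          params, dirichlet, nc)
  field <- structure(list(concentration = conc, gradient = NULL),
                     class = "morphogen_field")
  if (gradient) field$gradient <- vegf_gradient(field, mesh)
  field
}

# Sparse finite-volume steady-state solve (shared by the public API and
# the simulation loop's chemotaxis path). method = "direct" uses a Matrix
# sparse solve; "cg" uses the compiled Jacobi-preconditioned conjugate
# gradient (same SPD system, tolerance 1e-10; used in the hot loop where
# sparse-matrix construction overhead dominates).
solve_vegf_core <- function(adj, cen, A, is_src, params, dirichlet, nc,
                            method = c("direct", "cg")) {
  method <- match.arg(method)
  conc <- numeric(nc)
  if (params$s <= 0) return(conc)
  free <- setdiff(seq_len(nc), dirichlet)
  if (!length(free)) return(conc)
  src <- ifelse(is_src, params$s, 0) * A
  if (length(adj$a)) {
    dd <- sqrt((cen[adj$a, 1] - cen[adj$b, 1])^2 +
                 (cen[adj$a, 2] - cen[adj$b, 2])^2)
    w <- params$D * adj$shared_length / pmax(dd, 1e-9)
  } else {
    w <- numeric(0)
  }
  # Laplacian + degradation on free cells (Dirichlet cells are 0, so
  # cross terms to them only contribute to the diagonal)
  ia <- match(adj$a, free); ib <- match(adj$b, free)
  keep <- !is.na(ia) & !is.na(ib)
  nfree <- length(free)
  diag_w <- numeric(nfree)
  acc <- rowsum(c(w[!is.na(ia)], w[!is.na(ib)]),
                c(ia[!is.na(ia)], ib[!is.na(ib)]))
  diag_w[as.integer(rownames(acc))] <- acc
  dvec <- diag_w + params$k_deg * A[free]
  if (method == "cg") {
    conc[free] <- vegf_cg_cpp(ia[keep] - 1L, ib[keep] - 1L, w[keep],
                              dvec, src[free])
  } else {
    i <- c(seq_len(nfree), ia[keep], ib[keep])
    j <- c(seq_len(nfree), ib[keep], ia[keep])
    x <- c(dvec, -w[keep], -w[keep])
    M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nfree, nfree))
    sol <- as.numeric(Matrix::solve(M, src[free]))
    conc[free] <- pmax(sol, 0)
  }
  conc
}

#' VEGF gradient at each cell
#'
#' Least-squares plane fit of neighbouring concentrations against
#' centre-to-centre displacements, per cell; exact for linear fields.
#' Cells with fewer than two non-collinear neighbours get a zero vector.
#'
#' @param field a `morphogen_field` (its `concentration` is used).
#' @param mesh the [tissue_mesh()] the field was solved on.
#' @param cell optional single cell index; default all cells.
#' @param order neighbourhood order of the fit: 1 (adjacent cells,
#'   default) or 2 (neighbours of neighbours included; used for tip cells
#'   sitting in the zero-Dirichlet boundary layer, which a one-ring
#'   stencil cannot see past).
#' @return n x 2 gradient matrix (or length-2 vector for a single cell).
#' @export
vegf_gradient <- function(field, mesh, cell = NULL, order = 1) {
  cen <- cell_centroids(mesh)
  conc <- field$concentration
  adj <- adj_struct(mesh)
  nc <- n_cells(mesh)
  lv <- factor(adj$a, levels = seq_len(nc))
  lv2 <- factor(adj$b, levels = seq_len(nc))
  nbr <- c(split(adj$b, lv), split(adj$a, lv2))
  idx <- if (is.null(cell)) seq_len(nc) else cell
  G <- matrix(0, length(idx), 2)
  for (k in seq_along(idx)) {
    i <- idx[k]
    nb <- c(nbr[[i]], nbr[[i + nc]])
    if (order >= 2 && length(nb))
      nb <- setdiff(unique(c(nb, unlist(lapply(nb, function(j)
        c(nbr[[j]], nbr[[j + nc]]))))), i)
    if (length(nb) < 2) next
    X <- cen[nb, , drop = FALSE] - matrix(cen[i, ], length(nb), 2, byrow = TRUE)
    y <- conc[nb] - conc[i]
    XtX <- crossprod(X)
    if (abs(det(XtX)) < 1e-12 * (sum(X^2) / 2 + 1e-300)^2) next  # collinear
    G[k, ] <- solve(XtX, crossprod(X, y))
  }
  if (!is.null(cell) && length(cell) == 1) as.numeric(G) else G
}

#' Chemotactic motile forces on tip-cell vertices
#'
#' Each vertex of each endothelial tip cell receives an additional force
#' of magnitude `mu` along the unit VEGF gradient evaluated at the tip
#' cell; zero when the gradient magnitude is below the floor. Added to
#' the mechanical forces before [euler_step()]. When the field carries no
#' precomputed gradient, tip gradients are evaluated with a two-ring
#' stencil ([vegf_gradient()] with `order = 2`) so tips at the tissue
#' edge see past the zero-Dirichlet boundary layer.
#'
#' @param mesh a [tissue_mesh()].
#' @param field a solved `morphogen_field`.
#' @param params a [chemotaxis_params()].
#' @return n_vertices x 2 matrix of additive forces.
#' @export
tip_motile_forces <- function(mesh, field, params) {
  F <- matrix(0, n_vertices(mesh), 2)
  if (params$mu == 0) return(F)
  tips <- which(mesh$type == "endothelial_tip")
  if (!length(tips)) return(F)
  grad <- if (is.null(field$gradient)) {
    gm <- matrix(0, n_cells(mesh), 2)
    gm[tips, ] <- vegf_gradient(field, mesh, tips, order = 2)
    gm
  } else {
    field$gradient
  }
  for (cell in tips) {
    g <- grad[cell, ]
    gn <- sqrt(sum(g^2))
    if (gn < params$gradient_floor) next
    f <- params$mu * g / gn
    vs <- mesh$cells[[cell]]
    F[vs, 1] <- F[vs, 1] + f[1]
    F[vs, 2] <- F[vs, 2] + f[2]
  }
  F
}
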