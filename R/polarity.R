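#' Apico-basal polarity parameters
#'
#' Every epithelial cell carries a polarity vector `p`; its direction is
#' the basal-to-apical axis and its magnitude the polarisation degree.
#' Cues: a neighbouring endothelial cell or an unshared boundary edge
#' pushes `p` away from the cue at rate `rho`; a well-developed lumen or
#' a strongly polarised neighbour pulls `p` toward itself (the same rule
#' with negative rate); and each epithelial--epithelial contact adjusts
#' the magnitude by `-/+ eps * cos(theta)` with `theta` the angle between
#' `p` and the centre-to-centre direction (minus when the neighbour is
#' strongly polarised toward the cell -- apical poles repel -- plus
#' otherwise; `eq5_repulsion = FALSE` flips to the always-plus reading).
#'
#' @param rho polarisation rate for endothelial and lumen cues (1/h).
#' @param rho_boundary polarisation rate of the tissue-boundary cue;
#'   defaults to `rho` (equal rates; expose separately so the boundary
#'   cue can be weakened independently).
#' @param eps epithelial--epithelial polarisation rate (1/h).
#' @param p_star polarity magnitude above which a cell may create a lumen
#'   (also the "strongly polarised" threshold).
#' @param age_min minimum age (h) before a polarity-triggered division.
#' @param p_max cap on the polarity magnitude (> `p_star`).
#' @param developed_lumen_factor a lumen counts as well-developed when its
#'   area exceeds this multiple of the initial lumen target area.
#' @param eq5_repulsion sign convention switch (see above).
#' @return list of class `polarity_params`.
#' @export
polarity_params <- function(rho = 0.007, rho_boundary = rho,
                            eps = 0.004, p_star = 0.75,
                            age_min = 2, p_max = 1,
                            developed_lumen_factor = 2,
                            eq5_repulsion = TRUE) {
  stopifnot(rho >= 0, rho_boundary >= 0, eps >= 0, p_star >= 0,
            age_min >= 0, p_max > p_star)
  structure(list(rho = rho, rho_boundary = rho_boundary, eps = eps,
                 p_star = p_star, age_min = age_min,
                 p_max = p_max, developed_lumen_factor = developed_lumen_factor,
                 eq5_repulsion = eq5_repulsion),
            class = "polarity_params")
}

#' Lumen parameters
#'
#' @param A_init target area assigned to a newly created lumen cell.
#' @param grow lumen target-area growth coefficient (area per unit summed
#'   neighbour polarity per hour).
#' @return list of class `lumen_params`.
#' @export
lumen_params <- function(A_init = 0.1, grow = 0.004) {
  stopifnot(A_init > 0, grow >= 0)
  structure(list(A_init = A_init, grow = grow), class = "lumen_params")
}

#' Update polarity vectors of all epithelial cells
#'
#' One explicit time step of the polarity dynamics described in
#' [polarity_params()]. Endothelial and lumen cells carry zero polarity;
#' magnitudes are clamped to `p_max`.
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [polarity_params()].
#' @param dt time step (h).
#' @param lparams a [lumen_params()] (defines "well-developed" lumina).
#' @param geom optional precomputed geometry (list with `ed`, `adj`,
#'   `cen`, `areas`) shared across the step's updates by the simulation
#'   loop.
#' @return The mesh with updated `polarity`.
#' @export
update_polarity <- function(mesh, params, dt, lparams = lumen_params(),
                            geom = NULL) {
  stopifnot(dt > 0)
  cen <- if (is.null(geom)) cell_centroids(mesh) else geom$cen
  areas <- if (is.null(geom)) cell_areas(mesh) else geom$areas
  pol <- mesh$polarity
  pmag <- sqrt(pol[, 1]^2 + pol[, 2]^2)
  ep <- is_epithelial(mesh$type)
  strong <- ep & pmag > params$p_star
  dev_lumen <- mesh$type == "lumen" &
    areas > params$developed_lumen_factor * lparams$A_init

  adj <- if (is.null(geom)) adj_struct(mesh) else geom$adj
  pairs <- rbind(cbind(adj$a, adj$b), cbind(adj$b, adj$a))  # alpha, beta
  al <- pairs[, 1]; be <- pairs[, 2]
  keep <- ep[al]
  al <- al[keep]; be <- be[keep]
  d <- cen[al, , drop = FALSE] - cen[be, , drop = FALSE]    # beta -> alpha
  dn <- sqrt(d[, 1]^2 + d[, 2]^2); dn[dn == 0] <- 1
  ux <- d[, 1] / dn; uy <- d[, 2] / dn

  dpx <- numeric(n_cells(mesh)); dpy <- numeric(n_cells(mesh))
  acc <- function(idx, vx, vy) {
    if (!length(idx)) return()
    sx <- rowsum(vx, idx); sy <- rowsum(vy, idx)
    ii <- as.integer(rownames(sx))
    dpx[ii] <<- dpx[ii] + sx
    dpy[ii] <<- dpy[ii] + sy
  }
  # (i) away from endothelial neighbours
  sel <- is_endothelial(mesh$type[be])
  acc(al[sel], params$rho * ux[sel] * dt, params$rho * uy[sel] * dt)
  # (iii) toward well-developed lumina and strongly polarised neighbours
  sel <- dev_lumen[be] | strong[be]
  acc(al[sel], -params$rho * ux[sel] * dt, -params$rho * uy[sel] * dt)

  # (ii) away from unshared boundary edges (cue at the edge midpoint)
  ed <- if (is.null(geom)) edge_struct(mesh) else geom$ed
  bi <- which(ed$boundary & ep[ed$cell1])
  bed <- list(v1 = ed$v1[bi], v2 = ed$v2[bi], cell1 = ed$cell1[bi])
  if (length(bi)) {
    mid <- (mesh$pos[bed$v1, , drop = FALSE] + mesh$pos[bed$v2, , drop = FALSE]) / 2
    db <- cen[bed$cell1, , drop = FALSE] - mid
    dbn <- sqrt(db[, 1]^2 + db[, 2]^2); dbn[dbn == 0] <- 1
    acc(bed$cell1, params$rho_boundary * db[, 1] / dbn * dt,
        params$rho_boundary * db[, 2] / dbn * dt)
  }

  # epithelial-epithelial magnitude adjustment (Eq. 5 analogue)
  sel <- which(ep[be])
  if (length(sel)) {
    a2 <- al[sel]; b2 <- be[sel]
    pm <- pmag[a2]
    nz <- pm > 0
    if (any(nz)) {
      a2 <- a2[nz]; b2 <- b2[nz]; pm <- pm[nz]
      # direction alpha -> beta = -u
      cth <- (-ux[sel][nz] * pol[a2, 1] - uy[sel][nz] * pol[a2, 2]) / pm
      sgn <- rep(1, length(a2))
      if (params$eq5_repulsion) {
        # neighbour strongly polarised toward alpha: apical poles repel
        pb <- sqrt(pol[b2, 1]^2 + pol[b2, 2]^2)
        toward <- pb > params$p_star &
          (pol[b2, 1] * (cen[a2, 1] - cen[b2, 1]) +
             pol[b2, 2] * (cen[a2, 2] - cen[b2, 2])) > 0
        sgn[toward] <- -1
      }
      fac <- sgn * params$eps * cth * dt
      acc(a2, fac * pol[a2, 1] / pm, fac * pol[a2, 2] / pm)
    }
  }

  pol[, 1] <- pol[, 1] + dpx
  pol[, 2] <- pol[, 2] + dpy
  pol[!ep, ] <- 0
  mag <- sqrt(pol[, 1]^2 + pol[, 2]^2)
  over <- mag > params$p_max
  if (any(over)) pol[over, ] <- pol[over, ] * (params$p_max / mag[over])
  mesh$polarity <- pol
  mesh
}

#' Cells eligible for a polarity-triggered (lumen-creating) division
#'
#' Epithelial cells whose polarity magnitude exceeds `p_star`, older than
#' `age_min`, and not already in contact with a lumen cell (cells touching
#' a lumen feed its growth instead of creating another).
#'
#' @param mesh a [tissue_mesh()].
#' @param params a [polarity_params()].
#' @param adj optional precomputed [cell_adjacency()] structure.
#' @return Integer vector of eligible cell indices.
#' @export
check_polarised_division <- function(mesh, params, adj = NULL) {
  pmag <- sqrt(mesh$polarity[, 1]^2 + mesh$polarity[, 2]^2)
  cand <- which(is_epithelial(mesh$type) & pmag > params$p_star &
                  mesh$age > params$age_min)
  if (!length(cand)) return(integer(0))
  if (is.null(adj)) adj <- adj_struct(mesh)
  lum <- mesh$type == "lumen"
  touches_lumen <- unique(c(adj$a[lum[adj$b]], adj$b[lum[adj$a]]))
  setdiff(cand, touches_lumen)
}

#' Create a follicular lumen by polarised division
#'
#' The eligible mother divides along the line through its centroid
#' perpendicular to its polarity vector, so the daughters stack along
#' `p`. The distal daughter (farther along `+p`, i.e. at the apical pole)
#' becomes a lumen cell: zero polarity, never proliferates, target area
#' reset to `A_init`. The proximal daughter remains epithelial, replacing
#' the mother with her polarity vector.
#'
#' @param mesh a [tissue_mesh()].
#' @param cell eligible mother cell (see [check_polarised_division()]).
#' @param lparams a [lumen_params()].
#' @return `list(mesh, lumen_id, epithelial_id)`, or NULL when the
#'   division is geometrically impossible this step.
#' @export
create_lumen <- function(mesh, cell, lparams = lumen_params()) {
  p <- mesh$polarity[cell, ]
  pm <- sqrt(sum(p^2))
  if (pm == 0) stop("create_lumen requires a polarised mother cell")
  axis <- c(-p[2], p[1]) / pm            # division line perpendicular to p
  mother_pol <- mesh$polarity[cell, ]
  mother_age <- mesh$age[cell]
  mother_cycle <- mesh$cycle_duration[cell]
  div <- tryCatch(divide_cell(mesh, cell, axis = axis), error = function(e) NULL)
  if (is.null(div)) return(NULL)
  mesh <- div$mesh
  cen <- cell_centroids(mesh)
  proj <- as.numeric(cen[div$daughters, , drop = FALSE] %*% p)
  distal <- div$daughters[which.max(proj)]
  proximal <- setdiff(div$daughters, distal)
  mesh$type[distal] <- "lumen"
  mesh$polarity[distal, ] <- 0
  mesh$age[distal] <- 0
  mesh$generation[distal] <- 0L
  mesh$cycle_duration[distal] <- Inf
  mesh$A0[distal] <- lparams$A_init
  mesh$A0_ref[distal] <- lparams$A_init
  mesh$polarity[proximal, ] <- mother_pol
  mesh$age[proximal] <- mother_age
  mesh$cycle_duration[proximal] <- mother_cycle
  list(mesh = mesh, lumen_id = distal, epithelial_id = proximal)
}

#' Grow lumen target areas from neighbouring polarity
#'
#' Each lumen's target area increases by
#' `grow * sum(|p|) * dt` over its adjacent epithelial cells; the actual
#' area follows through the area-elasticity term of the tissue energy.
#' Target areas never decrease, so lumina ratchet toward their size
#' equilibrium.
#'
#' @param mesh a [tissue_mesh()].
#' @param lparams a [lumen_params()].
#' @param dt time step (h).
#' @param adj optional precomputed [cell_adjacency()] structure.
#' @return The mesh with updated lumen `A0`.
#' @export
grow_lumina <- function(mesh, lparams, dt, adj = NULL) {
  lum <- which(mesh$type == "lumen")
  if (!length(lum)) return(mesh)
  pmag <- sqrt(mesh$polarity[, 1]^2 + mesh$polarity[, 2]^2)
  if (is.null(adj)) adj <- adj_struct(mesh)
  for (L in lum) {
    nb <- c(adj$b[adj$a == L], adj$a[adj$b == L])
    nb <- nb[is_epithelial(mesh$type[nb])]
    if (!length(nb)) next
    dA <- lparams$grow * sum(pmag[nb]) * dt
    mesh$A0[L] <- mesh$A0[L] + dA
    mesh$A0_ref[L] <- mesh$A0_ref[L] + dA
  }
  mesh
}
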