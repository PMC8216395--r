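#' Cell centres from bounding-box tables
#'
#' Image-analysis platforms export one rectangle per detected cell; the
#' rectangle centre is the Voronoi seed. Degenerate boxes are dropped
#' with a warning, otherwise row order is preserved.
#'
#' @param table data frame with columns `xmin`, `ymin`, `xmax`, `ymax`
#'   and optionally `class` (`"epithelial"` / `"endothelial"`).
#' @return tibble with `x`, `y`, `class`.
#' @export
centres_from_boxes <- function(table) {
  if (!nrow(table))
    return(tibble::tibble(x = numeric(0), y = numeric(0), class = character(0)))
  ok <- table$xmax > table$xmin & table$ymax > table$ymin
  if (!all(ok)) {
    warning(sum(!ok), " degenerate bounding box(es) dropped")
    table <- table[ok, , drop = FALSE]
  }
  tibble::tibble(x = (table$xmin + table$xmax) / 2,
                 y = (table$ymin + table$ymax) / 2,
                 class = if ("class" %in% names(table))
                   as.character(table$class) else rep("epithelial", nrow(table)))
}

#' Read a cell-centre box table exported by an image-analysis platform
#'
#' Comma-separated with header `xmin,ymin,xmax,ymax,class`, coordinates
#' in image pixels with y increasing downward; y is flipped to the
#' mathematical y-up convention on import.
#'
#' @param path CSV file.
#' @param flip_y flip the y axis (default TRUE).
#' @return tibble of boxes ready for [centres_from_boxes()].
#' @export
read_seed_boxes <- function(path, flip_y = TRUE) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(tab)))
    stop("seed table must have columns xmin,ymin,xmax,ymax[,class]")
  if (flip_y) {
    ymax <- max(tab$ymax)
    y0 <- ymax - tab$ymax; y1 <- ymax - tab$ymin
    tab$ymin <- y0; tab$ymax <- y1
  }
  tibble::as_tibble(tab)
}

# Clip polygon (matrix of points, open ring) by half-plane n.x <= c.
clip_halfplane <- function(poly, n, cval) {
  if (is.null(poly) || nrow(poly) < 3) return(NULL)
  d <- poly %*% n - cval
  m <- nrow(poly)
  out <- matrix(0, m + 4, 2); k <- 0
  for (i in seq_len(m)) {
    j <- i %% m + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) { k <- k + 1; out[k, ] <- poly[i, ] }
    if ((di < 0 && dj > 0) || (di > 0 && dj < 0)) {
      t <- di / (di - dj)
      k <- k + 1; out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (k < 3) return(NULL)
  out[seq_len(k), , drop = FALSE]
}

# Voronoi region of seed i clipped to the boundary polygon: the boundary
# ring clipped by every perpendicular-bisector half-plane (nearest seeds
# first, stopping once no remaining seed can cut the region).
voronoi_region <- function(seeds, i, boundary) {
  s <- seeds[i, ]
  d2 <- (seeds[, 1] - s[1])^2 + (seeds[, 2] - s[2])^2
  ord <- order(d2)
  ord <- ord[ord != i]
  poly <- boundary
  for (j in ord) {
    if (is.null(poly)) return(NULL)
    rmax2 <- max((poly[, 1] - s[1])^2 + (poly[, 2] - s[2])^2)
    if (d2[j] > 4 * rmax2) break
    n <- seeds[j, ] - s
    cval <- sum(n * (s + seeds[j, ]) / 2)
    poly <- clip_halfplane(poly, n, cval)
  }
  poly
}

# Deduplicate near-identical ring points and build a shared vertex set.
snap_key <- function(xy, tol) {
  paste(round(xy[, 1] / tol), round(xy[, 2] / tol))
}

#' Build an initial condition from Voronoi seeds and a boundary polygon
#'
#' Computes the Voronoi tessellation of the seeds, clips every region by
#' the closed boundary annotation (which also closes the otherwise
#' infinite outer regions), rescales the tissue so the median epithelial
#' cell area is one, assigns cell types from the seed classes, and
#' returns a validated [tissue_mesh()]. Seeds outside the boundary are
#' rejected with a warning.
#'
#' @param seeds tibble/data frame with `x`, `y` and optionally `class`
#'   (default `"epithelial"`), e.g. from [centres_from_boxes()].
#' @param boundary two-column matrix: closed simple polygon (ordered ring,
#'   last point not repeated).
#' @param tip_ids,stalk_ids optional seed indices to label as endothelial
#'   tip / stalk cells (endothelial-class seeds default to stalk).
#' @param rescale rescale so the median epithelial area is 1 (default
#'   TRUE).
#' @param snap_tol vertex-merge tolerance, relative to the seed spacing.
#' @return A [tissue_mesh()]; epithelial cells are classified
#'   peripheral/central, ages zero.
#' @export
build_voronoi_ic <- function(seeds, boundary, tip_ids = integer(0),
                             stalk_ids = integer(0), rescale = TRUE,
                             snap_tol = 1e-6) {
  S <- cbind(seeds$x, seeds$y)
  boundary <- as.matrix(boundary)
  if (nrow(boundary) >= 2 &&
      all(boundary[1, ] == boundary[nrow(boundary), ]))
    boundary <- boundary[-nrow(boundary), , drop = FALSE]
  if (ring_signed_area(boundary, seq_len(nrow(boundary))) < 0)
    boundary <- boundary[rev(seq_len(nrow(boundary))), , drop = FALSE]
  inside <- points_in_polygon(S, boundary)
  if (!all(inside)) {
    warning(sum(!inside), " seed(s) outside the boundary rejected")
    keep <- which(inside)
    S <- S[keep, , drop = FALSE]
    seeds <- seeds[keep, , drop = FALSE]
    tip_ids <- match(intersect(tip_ids, keep), keep)
    stalk_ids <- match(intersect(stalk_ids, keep), keep)
  }
  n <- nrow(S)
  if (n < 3) stop("need at least 3 seeds inside the boundary")
  spread <- eigen(stats::cov(S), symmetric = TRUE, only.values = TRUE)$values
  if (spread[2] < 1e-12 * spread[1]) stop("seeds are collinear")

  regions <- lapply(seq_len(n), function(i) voronoi_region(S, i, boundary))
  empty <- vapply(regions, is.null, logical(1))
  if (any(empty)) {
    warning(sum(empty), " seed(s) produced empty clipped regions and were dropped")
    keep <- which(!empty)
    if (length(keep) < 3) stop("fewer than 3 surviving seeds")
    regions <- regions[keep]; seeds <- seeds[keep, , drop = FALSE]
    tip_ids <- match(intersect(tip_ids, keep), keep)
    stalk_ids <- match(intersect(stalk_ids, keep), keep)
    n <- length(keep)
  }

  scale_len <- sqrt(abs(ring_signed_area(boundary, seq_len(nrow(boundary)))) / n)
  tol <- snap_tol * scale_len
  # merge coincident vertices across regions
  allpts <- do.call(rbind, regions)
  keys <- snap_key(allpts, tol)
  uk <- !duplicated(keys)
  vmap <- match(keys, keys[uk])
  vpos <- allpts[uk, , drop = FALSE]
  offs <- c(0, cumsum(vapply(regions, nrow, integer(1))))
  rings <- lapply(seq_len(n), function(i) {
    r <- vmap[(offs[i] + 1):offs[i + 1]]
    r <- r[c(TRUE, r[-1] != r[-length(r)])]
    if (length(r) > 1 && r[1] == r[length(r)]) r <- r[-length(r)]
    r
  })
  if (any(lengths(rings) < 3)) stop("degenerate Voronoi cell after snapping")

  cls <- if ("class" %in% names(seeds)) seeds$class else rep("epithelial", n)
  type <- ifelse(cls == "endothelial", "endothelial_stalk", "epithelial_central")
  type[tip_ids] <- "endothelial_tip"
  type[stalk_ids] <- "endothelial_stalk"
  mesh <- tissue_mesh(vpos, rings, type)
  if (rescale) {
    ep <- is_epithelial(mesh$type)
    med <- stats::median(cell_areas(mesh)[ep])
    f <- 1 / sqrt(med)
    mesh$pos <- mesh$pos * f
    mesh$A0 <- mesh$A0 * f^2
  }
  mesh <- classify_peripherality(mesh)
  mesh$A0 <- cell_areas(mesh)
  mesh$A0_ref <- mesh$A0
  # co-circular seed degeneracies give >3-fold Voronoi vertices; track them
  # as rosettes (the first rearrangement sweep resolves them)
  deg <- vertex_cell_degree(mesh)
  bnd <- boundary_vertices(mesh)
  mesh$rosettes <- which((!bnd & deg > 3) | (bnd & deg > 2))
  mesh_check(mesh)
  mesh
}

# Even-odd point-in-polygon test (vectorised over points).
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Poisson-disc (dart-throwing) sampling inside a polygon, min distance r,
# with a margin from the boundary. Deterministic given the RNG state.
poisson_disc_in_polygon <- function(n, poly, r, margin, max_tries = 40000) {
  bb <- apply(poly, 2, range)
  pts <- matrix(NA_real_, n, 2)
  k <- 0
  shrunk <- poly  # margin enforced by distance-to-edges test
  for (try in seq_len(max_tries)) {
    p <- c(stats::runif(1, bb[1, 1], bb[2, 1]), stats::runif(1, bb[1, 2], bb[2, 2]))
    if (!points_in_polygon(matrix(p, 1), poly)) next
    if (polygon_edge_distance(p, poly) < margin) next
    if (k > 0) {
      d2 <- (pts[seq_len(k), 1] - p[1])^2 + (pts[seq_len(k), 2] - p[2])^2
      if (min(d2) < r^2) next
    }
    k <- k + 1
    pts[k, ] <- p
    if (k == n) return(pts)
  }
  stop("could not place ", n, " seeds; boundary too small for the spacing")
}

polygon_edge_distance <- function(p, poly) {
  n <- nrow(poly)
  dmin <- Inf
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    dmin <- min(dmin, point_segment_distance(p, poly[i, ], poly[j, ])$d)
  }
  dmin
}

# Smooth star-shaped blob boundary (low-order Fourier perturbation of a
# circle), emulating the outline of an E13.5 thyroid lobe cross-section.
random_blob <- function(R0, n_pts = 48, roughness = 0.12, modes = 2:4) {
  a <- stats::runif(length(modes), 0, roughness)
  ph <- stats::runif(length(modes), 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n_pts + 1)[-(n_pts + 1)]
  pert <- rep(0, length(th))
  for (k in seq_along(modes)) pert <- pert + a[k] * cos(modes[k] * th + ph[k])
  cbind(R0 * (1 + pert) * cos(th), R0 * (1 + pert) * sin(th))
}

#' Synthesise an E13.5-like initial condition
#'
#' Stands in for the image-derived initial condition no public dataset
#' provides: a compact blob of a few hundred non-polarised epithelial
#' cells (blue-noise seed spacing inside a smooth random boundary,
#' Voronoi-tessellated and clipped), with four endothelial tip + stalk
#' pairs extruded at well-separated peripheral sites, stalk vertices
#' anchored and corridors registered. Epithelial ages are assigned
#' uniformly at random within each cell's cycle so divisions
#' desynchronise. The endothelial area fraction of the result is checked
#' to be below 2 percent, matching the endothelial density measured at
#' E13.5. Fully deterministic given the RNG state (`set.seed`).
#'
#' @param n_epithelial number of epithelial cells (>= 20; default 200).
#' @param prolif a [proliferation_params()] used to initialise cycles.
#' @param endo_params an [endothelial_params()] (extrusion depth).
#' @param n_branches number of tip+stalk pairs (default 4).
#' @param max_endo_fraction admissible endothelial area fraction.
#' @return A validated [tissue_mesh()] ready for [simulate_tissue()].
#' @export
synthesize_e13_ic <- function(n_epithelial = 200,
                              prolif = proliferation_params(),
                              endo_params = endothelial_params(),
                              n_branches = 4,
                              max_endo_fraction = 0.02) {
  stopifnot(n_epithelial >= 20)
  R0 <- sqrt(n_epithelial / pi) * 1.05
  poly <- random_blob(R0)
  r <- 0.82
  seeds <- poisson_disc_in_polygon(n_epithelial, poly, r = r, margin = 0.35)
  mesh <- build_voronoi_ic(tibble::tibble(x = seeds[, 1], y = seeds[, 2]),
                           poly)
  if (n_cells(mesh) != n_epithelial)
    stop("seed placement failed to keep all ", n_epithelial, " cells")
  # extrusion depth scales with tissue size so the endothelial area
  # fraction constraint stays attainable for small tissues
  A_ep <- sum(cell_areas(mesh))
  endo_params$branch_depth <-
    min(endo_params$branch_depth,
        0.25 * max_endo_fraction * A_ep / max(n_branches, 1))
  for (b in seq_len(n_branches)) {
    res <- add_endothelial_branch(mesh, endo_params, clock = 0)
    if (!res$added) stop("could not place endothelial branch ", b)
    mesh <- res$mesh
  }
  mesh <- classify_peripherality(mesh)
  ep <- which(is_epithelial(mesh$type))
  mesh$cycle_duration[ep] <-
    cycle_duration_at_birth(mesh$type[ep], 0L, prolif)
  mesh$age[ep] <- stats::runif(length(ep), 0, mesh$cycle_duration[ep])
  # instantaneous target area = current area; the mature target is set so
  # the linear within-cycle growth law (half to full over one cycle)
  # continues smoothly from each cell's random age
  frac <- 0.5 + 0.5 * pmin(mesh$age[ep] / mesh$cycle_duration[ep], 1)
  mesh$A0_ref[ep] <- mesh$A0[ep] / frac
  A <- cell_areas(mesh)
  fr <- sum(A[is_endothelial(mesh$type)]) / sum(A)
  if (fr >= max_endo_fraction)
    stop("endothelial fraction ", signif(fr, 3),
         " exceeds the E13.5 constraint; increase n_epithelial")
  mesh_check(mesh)
  mesh
}
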