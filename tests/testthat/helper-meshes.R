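# Fixture meshes built in code.

unit_square_mesh <- function(type = "epithelial_central") {
  tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), list(1:4), type)
}

two_cell_mesh <- function(types = c("epithelial_central", "epithelial_central")) {
  pos <- rbind(c(0, 0), c(1, 0), c(2, 0), c(2, 1), c(1, 1), c(0, 1))
  tissue_mesh(pos, list(c(1, 2, 5, 6), c(2, 3, 4, 5)), types)
}

# 7-cell honeycomb flower: central hexagon surrounded by six hexagons.
honeycomb_flower <- function(type = "epithelial_central") {
  hexa <- function(cx, cy) {
    th <- pi / 6 + (0:5) * pi / 3
    cbind(cx + cos(th) / sqrt(3), cy + sin(th) / sqrt(3))
  }
  centres <- rbind(c(0, 0), t(vapply(0:5, function(k)
    c(cos(k * pi / 3), sin(k * pi / 3)), numeric(2))))
  pts <- NULL; rings <- list()
  key <- character(0)
  for (i in seq_len(nrow(centres))) {
    h <- hexa(centres[i, 1], centres[i, 2])
    ids <- integer(6)
    for (j in 1:6) {
      k <- paste(round(h[j, 1], 9), round(h[j, 2], 9))
      m <- match(k, key)
      if (is.na(m)) {
        key <- c(key, k)
        pts <- rbind(pts, h[j, ])
        m <- length(key)
      }
      ids[j] <- m
    }
    rings[[i]] <- ids
  }
  tissue_mesh(pts, rings, rep(type, 7))
}

# Random Voronoi mesh of n epithelial cells in a square (valid tissue).
random_voronoi_mesh <- function(n = 25, seed = 1, side = 6) {
  set.seed(seed)
  pts <- cbind(stats::runif(n, 0, side), stats::runif(n, 0, side))
  bnd <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  build_voronoi_ic(tibble::tibble(x = pts[, 1], y = pts[, 2]), bnd,
                   rescale = FALSE)
}

# Canonical 4-cell T1 configuration: short central vertical edge shared by
# left/right cells, flanked by bottom and top cells.
t1_four_cell_mesh <- function(eps = 0.004) {
  pos <- rbind(
    c(0, -eps / 2),   # 1: a (lower end of the short edge)
    c(0, eps / 2),    # 2: b (upper end)
    c(-1, -1), c(1, -1),   # 3,4 bottom outer
    c(1, 1), c(-1, 1),     # 5,6 top outer
    c(-1.6, 0), c(1.6, 0)) # 7,8 side outer
  cells <- list(
    c(3, 4, 1),            # bottom cell (contains a)
    c(5, 6, 2),            # top cell (contains b)
    c(1, 2, 6, 7, 3),      # left cell (shares edge a-b)
    c(2, 1, 4, 8, 5))      # right cell (shares edge a-b)
  tissue_mesh(pos, cells, rep("epithelial_central", 4))
}

# Central-difference gradient of the tissue energy.
numeric_energy_gradient <- function(mesh, params, h = 1e-6) {
  G <- mesh$pos * 0
  for (i in seq_len(nrow(mesh$pos))) {
    for (j in 1:2) {
      mp <- mesh; mp$pos[i, j] <- mp$pos[i, j] + h
      mm <- mesh; mm$pos[i, j] <- mm$pos[i, j] - h
      G[i, j] <- (total_energy(mp, params) - total_energy(mm, params)) / (2 * h)
    }
  }
  G
}

expect_valid_mesh <- function(mesh) {
  expect_true(mesh_check(mesh))
}
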