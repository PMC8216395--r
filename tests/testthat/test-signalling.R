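test_that("zero production (VEGFA knockout) gives an identically zero field", {
  m <- random_voronoi_mesh(20, seed = 4)
  f <- solve_vegf_field(m, morphogen_params(s = 0))
  expect_true(all(f$concentration == 0))
  expect_true(all(f$gradient == 0))
})

test_that("the 1D chain solve converges to the cosh closed form", {
  chain_mesh <- function(N) {
    pos <- NULL; cells <- list()
    for (i in seq_len(N)) {
      pos <- rbind(pos, c(i - 1, 0), c(i, 0), c(i, 1), c(i - 1, 1))
    }
    # share vertices between neighbouring squares
    allp <- NULL; key <- character(0); rings <- list()
    for (i in seq_len(N)) {
      sq <- rbind(c(i - 1, 0), c(i, 0), c(i, 1), c(i - 1, 1))
      ids <- integer(4)
      for (j in 1:4) {
        k <- paste(sq[j, 1], sq[j, 2])
        mm <- match(k, key)
        if (is.na(mm)) { key <- c(key, k); allp <- rbind(allp, sq[j, ]); mm <- length(key) }
        ids[j] <- mm
      }
      rings[[i]] <- ids
    }
    tissue_mesh(allp, rings, rep("epithelial_central", N))
  }
  D <- 4; k <- 1; s <- 1   # diffusion length of two cells: well resolved
  closed_form <- function(x, L) {
    (s / k) * (1 - cosh(sqrt(k / D) * (x - L / 2)) / cosh(sqrt(k / D) * L / 2))
  }
  err <- vapply(c(20, 40, 80), function(N) {
    m <- chain_mesh(N)
    # Dirichlet pinned at the two chain ends (every cell in a 1D chain
    # touches the tissue boundary, so the default set would zero it all)
    f <- solve_vegf_field(m, morphogen_params(D = D, s = s, k_deg = k),
                          dirichlet = c(1, N))
    x <- cell_centroids(m)[, 1]
    sqrt(mean((f$concentration - closed_form(x, N))^2)) / (s / k)
  }, numeric(1))
  expect_lt(err[3], 0.06)
  expect_true(all(diff(err) < 0))   # error decreases under refinement
})

test_that("the field is nonnegative, bounded by s/k, and zero on the boundary", {
  m <- random_voronoi_mesh(40, seed = 6)
  mp <- morphogen_params(D = 0.5, s = 2, k_deg = 0.8)
  f <- solve_vegf_field(m, mp)
  expect_true(all(f$concentration >= 0))
  expect_lte(max(f$concentration), mp$s / mp$k_deg + 1e-9)
  ed <- mesh_edges(m)
  expect_true(all(f$concentration[unique(ed$cell1[ed$boundary])] == 0))
  expect_gt(max(f$concentration), 0)
})

test_that("gradient fits are exact for linear fields and zero for constants", {
  m <- random_voronoi_mesh(30, seed = 9)
  cen <- cell_centroids(m)
  f <- structure(list(concentration = 2 * cen[, 1]), class = "morphogen_field")
  interior <- setdiff(seq_len(n_cells(m)),
                      unique(mesh_edges(m)$cell1[mesh_edges(m)$boundary]))
  g <- vegf_gradient(f, m)
  for (i in interior)
    expect_equal(g[i, ], c(2, 0), tolerance = 1e-6)
  fc <- structure(list(concentration = rep(3, n_cells(m))),
                  class = "morphogen_field")
  expect_true(all(abs(vegf_gradient(fc, m)) < 1e-9))
})

test_that("the gradient vanishes at the centre of a symmetric disc", {
  # rotationally symmetric wheel: hub cell surrounded by identical sectors
  n <- 8
  th <- 2 * pi * (0:(n - 1)) / n
  hub <- cbind(0.4 * cos(th), 0.4 * sin(th))
  rim <- cbind(1.6 * cos(th), 1.6 * sin(th))
  pos <- rbind(hub, rim)
  cells <- c(list(1:n), lapply(seq_len(n), function(i) {
    j <- i %% n + 1L
    c(i, n + i, n + j, j)
  }))
  m <- tissue_mesh(pos, cells, rep("epithelial_central", n + 1))
  f <- solve_vegf_field(m, morphogen_params())
  expect_lt(sqrt(sum(f$gradient[1, ]^2)), 1e-6)
})

test_that("rotating the mesh rotates the solved gradient", {
  m <- random_voronoi_mesh(25, seed = 14)
  mp <- morphogen_params()
  f1 <- solve_vegf_field(m, mp)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  m2 <- m; m2$pos <- m$pos %*% t(R)
  f2 <- solve_vegf_field(m2, mp)
  expect_equal(f2$concentration, f1$concentration, tolerance = 1e-8)
  expect_equal(f2$gradient, f1$gradient %*% t(R), tolerance = 1e-6)
})

test_that("tip motile forces follow the gradient and respect mu = 0", {
  m <- random_voronoi_mesh(35, seed = 15)
  m <- classify_peripherality(m)
  ed <- mesh_edges(m)
  tip <- ed$cell1[ed$boundary][1]
  m$type[tip] <- "endothelial_tip"
  f <- solve_vegf_field(m, morphogen_params(), gradient = FALSE)
  F0 <- tip_motile_forces(m, f, chemotaxis_params(mu = 0))
  expect_true(all(F0 == 0))
  F <- tip_motile_forces(m, f, chemotaxis_params(mu = 0.4))
  vs <- m$cells[[tip]]
  expect_true(all(rowSums(F[vs, , drop = FALSE]^2) > 0))
  expect_true(all(F[-vs, ] == 0))
  # the added force points toward higher concentration: moving the tip
  # centroid along the force must increase the interpolated field
  g <- vegf_gradient(f, m, tip, order = 2)
  fdir <- F[vs[1], ] / sqrt(sum(F[vs[1], ]^2))
  expect_equal(sum(fdir * g / sqrt(sum(g^2))), 1, tolerance = 1e-9)
  # and per-vertex magnitude is mu
  expect_equal(sqrt(sum(F[vs[1], ]^2)), 0.4, tolerance = 1e-12)
  # the gradient seen by the boundary tip points into the tissue interior
  cen <- cell_centroids(m)
  inward <- colMeans(cen) - cen[tip, ]
  expect_gt(sum(g * inward), 0)
})

test_that("CG and direct solvers agree on the same system", {
  m <- random_voronoi_mesh(40, seed = 23)
  mp <- morphogen_params(D = 1.3, s = 0.7, k_deg = 0.5)
  ed <- thyromorph:::edge_struct(m)
  adj <- thyromorph:::adj_struct(m, ed)
  cen <- cell_centroids(m); A <- cell_areas(m)
  dir <- unique(ed$cell1[ed$boundary])
  c1 <- thyromorph:::solve_vegf_core(adj, cen, A,
                                     thyromorph:::is_epithelial(m$type),
                                     mp, dir, n_cells(m), method = "direct")
  c2 <- thyromorph:::solve_vegf_core(adj, cen, A,
                                     thyromorph:::is_epithelial(m$type),
                                     mp, dir, n_cells(m), method = "cg")
  expect_equal(c2, c1, tolerance = 1e-8)
})
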