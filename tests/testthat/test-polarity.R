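test_that("the endothelial cue increments polarity by rho * unit vector * dt", {
  # epithelial cell at origin-ish, endothelial neighbour offset by (-3, -4)
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
               c(1 - 3, -4), c(1 - 3 + 1, -4))
  # build two squares sharing edge 1-2 is complicated; use two_cell_mesh
  m <- two_cell_mesh(c("epithelial_central", "endothelial_tip"))
  pp <- polarity_params(rho = 1, eps = 0)
  d <- cell_centroids(m)[1, ] - cell_centroids(m)[2, ]   # beta -> alpha
  u <- d / sqrt(sum(d^2))
  # exclude the boundary cue by comparing against a run with rho matched
  m$polarity[, ] <- 0
  m2 <- update_polarity(m, pp, dt = 0.1)
  # cell 1 receives the endothelial cue plus its boundary-edge cues
  ed <- thyromorph:::edge_struct(m)
  bidx <- which(ed$boundary & ed$cell1 == 1)
  mid <- (m$pos[ed$v1[bidx], , drop = FALSE] +
            m$pos[ed$v2[bidx], , drop = FALSE]) / 2
  db <- matrix(cell_centroids(m)[1, ], nrow(mid), 2, byrow = TRUE) - mid
  db <- db / sqrt(rowSums(db^2))
  expected <- 0.1 * (u + colSums(db))
  expect_equal(m2$polarity[1, ], expected, tolerance = 1e-9)
  # endothelial cells carry no polarity
  expect_equal(m2$polarity[2, ], c(0, 0))
})

test_that("an epithelial cell polarises away from an endothelial neighbour due west", {
  m <- honeycomb_flower()
  m$type[5] <- "endothelial_tip"   # petal centred due west of the hub
  cen <- cell_centroids(m)
  stopifnot(cen[5, 1] < cen[1, 1], abs(cen[5, 2] - cen[1, 2]) < 1e-9)
  pp <- polarity_params(rho = 0.5, eps = 0)
  m2 <- update_polarity(m, pp, dt = 0.2)
  # hub (interior, no boundary edges): only the endothelial cue acts
  p <- m2$polarity[1, ]
  expect_gt(p[1], 0)
  expect_lt(abs(p[2]), 1e-9 * abs(p[1]) + 1e-12)
})

test_that("eq-5 style neighbour term vanishes at a right angle", {
  m <- two_cell_mesh(c("epithelial_central", "epithelial_central"))
  # polarity of cell 1 perpendicular to the centre-centre axis (x axis)
  m$polarity[1, ] <- c(0, 0.4)
  pp <- polarity_params(rho = 0, eps = 1, eq5_repulsion = FALSE)
  m2 <- update_polarity(m, pp, dt = 0.1)
  expect_equal(sqrt(sum(m2$polarity[1, ]^2)), 0.4, tolerance = 1e-9)
})

test_that("polarity magnitude is capped and strong cues attract", {
  m <- two_cell_mesh(c("epithelial_central", "epithelial_central"))
  m$polarity[2, ] <- c(-0.9, 0)       # strongly polarised toward cell 1
  pp <- polarity_params(rho = 100, eps = 0, p_star = 0.6, p_max = 1)
  m2 <- update_polarity(m, pp, dt = 1)
  expect_lte(sqrt(sum(m2$polarity[1, ]^2)), 1 + 1e-9)
  expect_lte(sqrt(sum(m2$polarity[2, ]^2)), 1 + 1e-9)
})

test_that("mirror symmetry: reflecting the mesh reflects the polarity update", {
  m <- random_voronoi_mesh(18, seed = 41)
  m <- classify_peripherality(m)
  m$type[2] <- "endothelial_tip"
  set.seed(2); m$polarity <- matrix(stats::rnorm(2 * n_cells(m), 0, 0.2),
                                    ncol = 2)
  pp <- polarity_params()
  m1 <- update_polarity(m, pp, dt = 0.05)
  mr <- m
  mr$pos[, 1] <- -mr$pos[, 1]
  mr$cells <- lapply(mr$cells, rev)     # keep CCW after reflection
  mr$polarity[, 1] <- -mr$polarity[, 1]
  m2 <- update_polarity(mr, pp, dt = 0.05)
  expect_equal(m2$polarity[, 1], -m1$polarity[, 1], tolerance = 1e-9)
  expect_equal(m2$polarity[, 2], m1$polarity[, 2], tolerance = 1e-9)
})

test_that("eligibility for lumen-creating division follows the rules", {
  m <- classify_peripherality(honeycomb_flower())
  pp <- polarity_params(p_star = 0.6, age_min = 2)
  m$age <- rep(10, 7)
  m$polarity[1, ] <- c(0.3, 0)               # below threshold
  expect_length(check_polarised_division(m, pp), 0)
  m$polarity[1, ] <- c(0.9, 0)               # above threshold, old enough
  expect_equal(check_polarised_division(m, pp), 1L)
  m$age[1] <- 1                              # too young
  expect_length(check_polarised_division(m, pp), 0)
  m$age[1] <- 10
  m$type[2] <- "lumen"                       # touching a lumen: excluded
  expect_length(check_polarised_division(m, pp), 0)
})

test_that("lumen creation divides perpendicular to p, distal daughter becomes lumen", {
  m <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(1, 2), c(0, 2)), list(1:4),
                   "epithelial_peripheral")
  m$polarity[1, ] <- c(0, 0.8)
  m$age <- 10
  lp <- lumen_params(A_init = 0.1)
  res <- create_lumen(m, 1, lp)
  expect_false(is.null(res))
  cen <- cell_centroids(res$mesh)
  # division line horizontal: daughters stacked along y; upper one is lumen
  expect_gt(cen[res$lumen_id, 2], cen[res$epithelial_id, 2])
  expect_equal(res$mesh$type[res$lumen_id], "lumen")
  expect_equal(res$mesh$A0[res$lumen_id], 0.1)
  expect_equal(res$mesh$cycle_duration[res$lumen_id], Inf)
  expect_equal(res$mesh$polarity[res$lumen_id, ], c(0, 0))
  # proximal daughter keeps the mother's polarity vector
  expect_equal(res$mesh$polarity[res$epithelial_id, ], c(0, 0.8))
  expect_valid_mesh(res$mesh)
})

test_that("lumen target areas grow with neighbour polarity and never shrink", {
  m <- classify_peripherality(honeycomb_flower())
  m$type[1] <- "lumen"
  m$A0[1] <- 0.1; m$A0_ref[1] <- 0.1
  for (i in 2:5) m$polarity[i, ] <- c(0.5, 0)
  lp <- lumen_params(A_init = 0.1, grow = 0.1)
  m2 <- grow_lumina(m, lp, dt = 0.001)
  expect_equal(m2$A0[1], 0.1 + 0.1 * 2.0 * 0.001, tolerance = 1e-12)
  # no polarised neighbours: no growth
  m$polarity[, ] <- 0
  m3 <- grow_lumina(m, lp, dt = 0.5)
  expect_equal(m3$A0[1], 0.1)
})
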