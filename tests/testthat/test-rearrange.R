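test_that("T1 reconnects the canonical four-cell configuration", {
  m <- t1_four_cell_mesh(eps = 0.004)
  ed <- mesh_edges(m)
  short <- ed[ed$length < 0.01 & !ed$boundary, ]
  expect_equal(nrow(short), 1)
  m2 <- apply_t1(m, c(short$v1, short$v2))
  expect_false(isTRUE(attr(m2, "t1_failed")))
  expect_equal(n_cells(m2), 4)
  # former non-neighbours (bottom cell 1 and top cell 2) now share an edge
  adj <- cell_adjacency(m2)
  pairs <- paste(adj$a, adj$b)
  expect_true("1 2" %in% pairs)
  # the cells that shared the short edge (3 and 4) are no longer adjacent
  expect_false("3 4" %in% pairs)
  expect_valid_mesh(m2)
  # new edge length equals the post-T1 setting
  ed2 <- mesh_edges(m2)
  expect_equal(min(ed2$length), 1.5 * 0.01, tolerance = 1e-9)
})

test_that("T1 is a no-op on long edges", {
  m <- t1_four_cell_mesh(eps = 0.5)
  ed <- mesh_edges(m)
  i <- which(!ed$boundary)[1]
  m2 <- apply_t1(m, c(ed$v1[i], ed$v2[i]))
  expect_identical(m2$cells, m$cells)
})

test_that("repeated sweeps keep cells simple on a perturbed mesh", {
  m <- random_voronoi_mesh(20, seed = 5)
  set.seed(5)
  m$pos <- m$pos + matrix(stats::rnorm(2 * n_vertices(m), 0, 0.002),
                          ncol = 2)
  for (k in 1:3) m <- rearrangement_sweep(m)
  for (i in seq_len(n_cells(m)))
    expect_true(thyromorph:::ring_is_simple(m$pos, m$cells[[i]]))
  expect_valid_mesh(m)
})

test_that("T2 removes a small triangle and conserves outside area", {
  # small triangle nested between three quadrilaterals (outer triangle)
  ang <- c(90, 210, 330) * pi / 180
  tin <- 0.012 * cbind(cos(ang), sin(ang))
  tout <- 2 * cbind(cos(ang), sin(ang))
  pos <- rbind(tin, tout)   # 1:3 inner, 4:6 outer
  cells <- list(c(1, 2, 3),
                c(4, 5, 2, 1), c(5, 6, 3, 2), c(6, 4, 1, 3))
  m <- tissue_mesh(pos, cells, rep("epithelial_central", 4))
  mesh_check(m, check_simple = FALSE)
  A_before <- sum(cell_areas(m))
  tri_area <- cell_area(m, 1)
  nv <- n_vertices(m)
  A_nb_before <- cell_areas(m)[2:4]
  m2 <- apply_t2(m, 1, area_threshold = 0.001)
  expect_equal(n_cells(m2), 3)
  expect_equal(n_vertices(m2), nv - 2)
  # bookkeeping: the neighbours annex exactly the removed triangle (the
  # centroid closure tiles it), so the total tissue area is conserved
  expect_equal(sum(cell_areas(m2)), A_before, tolerance = 1e-9)
  expect_equal(sum(cell_areas(m2)) - sum(A_nb_before), tri_area,
               tolerance = 1e-9)
  expect_valid_mesh(m2)
})

test_that("T2 respects the threshold, lumen exemption and triangle contract", {
  m <- t1_four_cell_mesh(eps = 0.5)   # cells 1 and 2 are triangles
  expect_identical(apply_t2(m, 1, area_threshold = 1e-6)$cells, m$cells)
  m$type[1] <- "lumen"
  expect_identical(apply_t2(m, 1, area_threshold = 1e6)$cells, m$cells)
  expect_error(apply_t2(m, 3, area_threshold = 1), "non-triangle")
})

test_that("T3 merges a near-touching boundary vertex into the facing edge", {
  # two separate cells: a square and a triangle whose apex approaches the
  # square's right edge from outside
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
               c(1.0004, 0.5), c(2, 0.2), c(2, 0.8))
  m <- tissue_mesh(pos, list(1:4, c(5, 6, 7)),
                   c("epithelial_central", "epithelial_central"))
  m2 <- apply_t3(m, 5, c(2, 3), tol = 1e-3)
  expect_true(5 %in% m2$cells[[1]])
  # overlapped edge split in two: the square gained a vertex
  expect_equal(length(m2$cells[[1]]), 5)
  # vertex snapped onto the segment
  expect_equal(m2$pos[5, 1], 1)
  # no pair of boundary edges intersects after the merge
  ed <- mesh_edges(m2)
  bed <- ed[ed$boundary, ]
  for (i in seq_len(nrow(bed) - 1)) {
    for (j in (i + 1):nrow(bed)) {
      if (length(intersect(c(bed$v1[i], bed$v2[i]),
                           c(bed$v1[j], bed$v2[j])))) next
      expect_false(thyromorph:::segments_intersect(
        m2$pos[bed$v1[i], ], m2$pos[bed$v2[i], ],
        m2$pos[bed$v1[j], ], m2$pos[bed$v2[j], ]))
    }
  }
})

test_that("T3 is a no-op beyond tolerance and rejects interior vertices", {
  pos <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
               c(1.1, 0.5), c(2, 0.2), c(2, 0.8))
  m <- tissue_mesh(pos, list(1:4, c(5, 6, 7)),
                   c("epithelial_central", "epithelial_central"))
  m2 <- apply_t3(m, 5, c(2, 3), tol = 1e-3)
  expect_identical(m2$cells, m$cells)
})

test_that("rosette resolution restores degree-3 vertices", {
  # four quadrants meeting at one central vertex (degree 4 rosette)
  pos <- rbind(c(0, 0),
               c(2, 0), c(2, 2), c(0, 2), c(-2, 2), c(-2, 0),
               c(-2, -2), c(0, -2), c(2, -2))
  cells <- list(c(1, 2, 3, 4), c(1, 4, 5, 6), c(1, 6, 7, 8), c(1, 8, 9, 2))
  m <- tissue_mesh(pos, cells, rep("epithelial_central", 4))
  m <- thyromorph:::track_violations(m)
  expect_true(1 %in% m$rosettes)
  m2 <- resolve_rosettes(m)
  expect_length(m2$rosettes, 0)
  deg <- thyromorph:::vertex_cell_degree(m2)
  bnd <- boundary_vertices(m2)
  expect_true(all(deg[!bnd & deg > 0] == 3))
  expect_valid_mesh(m2)
})

test_that("sweeps are idempotent and fix a short edge", {
  m <- random_voronoi_mesh(15, seed = 2)
  m2 <- rearrangement_sweep(m)
  m3 <- rearrangement_sweep(m2)
  expect_identical(m3$cells, m2$cells)
  expect_identical(m3$pos, m2$pos)
  ms <- t1_four_cell_mesh(eps = 0.004)
  ms2 <- rearrangement_sweep(ms)
  ed <- mesh_edges(ms2)
  expect_gte(min(ed$length), 0.01)
  expect_valid_mesh(ms2)
})
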