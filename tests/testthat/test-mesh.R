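test_that("shoelace areas match known polygons and a geometry oracle", {
  m <- unit_square_mesh()
  expect_equal(cell_area(m, 1), 1.0)
  tri <- tissue_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), list(1:3),
                     "epithelial_central")
  expect_equal(cell_area(tri, 1), 0.5)
  # random convex 8-gon vs a triangle-fan decomposition oracle
  set.seed(42)
  th <- sort(stats::runif(8, 0, 2 * pi))
  r <- stats::runif(8, 0.5, 2)
  pts <- cbind(r * cos(th), r * sin(th))
  m8 <- tissue_mesh(pts, list(1:8), "epithelial_central")
  fan <- sum(vapply(2:7, function(i) {
    0.5 * ((pts[i, 1] - pts[1, 1]) * (pts[i + 1, 2] - pts[1, 2]) -
             (pts[i + 1, 1] - pts[1, 1]) * (pts[i, 2] - pts[1, 2]))
  }, numeric(1)))
  expect_equal(cell_area(m8, 1), abs(fan), tolerance = 1e-12)
})

test_that("degenerate polygons are rejected", {
  m <- unit_square_mesh()
  m$cells[[1]] <- c(1L, 2L)
  expect_error(cell_area(m, 1), "degenerate")
})

test_that("edge table classifies shared and boundary edges", {
  m <- two_cell_mesh()
  ed <- mesh_edges(m)
  expect_equal(nrow(ed), 7)
  shared <- ed[!ed$boundary, ]
  expect_equal(nrow(shared), 1)
  expect_setequal(c(shared$cell1, shared$cell2), c(1, 2))
  expect_equal(sum(ed$boundary), 6)
})

test_that("vertex degrees and boundary flags satisfy the mesh contract", {
  m <- honeycomb_flower()
  deg <- thyromorph:::vertex_cell_degree(m)
  bnd <- boundary_vertices(m)
  expect_true(all(deg[!bnd] == 3))
  expect_true(all(deg[bnd] %in% 1:2))
  expect_valid_mesh(m)
})

test_that("mesh_check detects corrupt meshes", {
  m <- two_cell_mesh()
  bad <- m
  bad$cells[[1]] <- rev(bad$cells[[1]])   # clockwise
  expect_error(mesh_check(bad), "counter-clockwise")
  bad2 <- m
  bad2$pos[1, 1] <- NaN
  expect_error(mesh_check(bad2), "non-finite")
})

test_that("cell adjacency aggregates shared edge lengths", {
  m <- honeycomb_flower()
  adj <- cell_adjacency(m)
  # central cell 1 touches all six petals
  nb1 <- sort(unique(c(adj$b[adj$a == 1], adj$a[adj$b == 1])))
  expect_equal(nb1, 2:7)
  expect_true(all(adj$shared_length > 0))
})

test_that("JSON snapshot round-trips the full state", {
  m <- random_voronoi_mesh(12, seed = 3)
  ed <- mesh_edges(m)
  stalk <- ed$cell1[ed$boundary][1]
  m$type[stalk] <- "endothelial_stalk"
  m$type[setdiff(c(2, 5), stalk)[1]] <- "lumen"
  m$polarity[1, ] <- c(0.3, -0.2)
  m$age <- seq_len(n_cells(m)) / 10
  m <- register_endo_boundary(m, stalk)
  f <- tempfile(fileext = ".json")
  write_mesh_json(m, f)
  m2 <- read_mesh_json(f)
  expect_equal(m2$pos, m$pos)
  expect_identical(lapply(m2$cells, as.integer), lapply(m$cells, as.integer))
  expect_identical(m2$type, m$type)
  expect_equal(m2$polarity, m$polarity, ignore_attr = TRUE)
  expect_equal(m2$A0_ref, m$A0_ref)
  expect_equal(length(m2$boundaries), length(m$boundaries))
  unlink(f)
})

test_that("VTK snapshots are well-formed polydata", {
  m <- unit_square_mesh()
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f)
  lines <- readLines(f)
  expect_true(any(grepl("^DATASET POLYDATA", lines)))
  expect_true(any(grepl("^POINTS 4 double", lines)))
  expect_true(any(grepl("^POLYGONS 1 5", lines)))
  expect_true(any(grepl("cell_type", lines)))
  unlink(f)
})
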