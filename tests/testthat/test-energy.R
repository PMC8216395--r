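test_that("total energy reproduces a hand-evaluated single-cell case", {
  m <- unit_square_mesh()
  m$A0 <- 1
  p <- energy_params(K = 1, gamma = 0.5, lambda = 0.1)
  # area term 0, line tension 4 * 0.1, contractility 0.5 * 16 / 2
  expect_equal(total_energy(m, p), 4.4)
  expect_equal(total_energy(m, energy_params(K = 0, gamma = 0, lambda = 0)), 0)
})

test_that("two-cell energy matches a naive per-term re-summation", {
  m <- two_cell_mesh(c("epithelial_central", "endothelial_tip"))
  p <- energy_params(K = 2, gamma = 0.3, lambda = 0.2)
  p <- set_lambda(p, "epithelial_central", "endothelial_tip", -0.05)
  A <- cell_areas(m); P <- cell_perimeters(m)
  ed <- mesh_edges(m)
  lam <- ifelse(ed$boundary, 0.2, -0.05)
  naive <- sum(2 / 2 * (A - m$A0)^2) + sum(lam * ed$length) +
    sum(0.3 / 2 * P^2)
  expect_equal(total_energy(m, p), naive, tolerance = 1e-12)
})

test_that("a missing line-tension entry is a configuration error", {
  m <- two_cell_mesh()
  p <- energy_params()
  p$lambda["epithelial_central", "BOUNDARY"] <- NA
  p$lambda["BOUNDARY", "epithelial_central"] <- NA
  expect_error(total_energy(m, p), "line-tension")
})

test_that("forces equal minus the numeric energy gradient (oracle)", {
  # hand-checked square: perimeter term only, force on corner = (2, 2)
  m <- unit_square_mesh(); m$A0 <- 1
  p0 <- energy_params(K = 1, gamma = 0.5, lambda = 0)
  expect_equal(vertex_forces(m, p0)[1, ], c(2, 2), tolerance = 1e-12)

  p <- energy_params(K = 1.5, gamma = 0.12, lambda = 0.08)
  for (seed in 1:6) {
    mesh <- random_voronoi_mesh(12, seed = seed)
    F <- vertex_forces(mesh, p)
    G <- numeric_energy_gradient(mesh, p)
    expect_lt(max(abs(F + G)), 1e-5)
  }
})

test_that("forces vanish at the energy minimum", {
  # single square with perimeter contractility: minimising
  # K/2 (L^2 - A0)^2 + Gamma/2 (4L)^2 over the side length gives
  # L^2 = A0 - 8 Gamma / K, and by symmetry that square is a full
  # critical point of the tissue energy
  K <- 1; G <- 0.04
  L <- sqrt(1 - 8 * G / K)
  m <- tissue_mesh(rbind(c(0, 0), c(L, 0), c(L, L), c(0, L)), list(1:4),
                   "epithelial_central", A0 = 1)
  p <- energy_params(K = K, gamma = G, lambda = 0)
  expect_lt(max(abs(vertex_forces(m, p))), 1e-8)
})

test_that("euler_step moves free vertices, pins fixed ones, advances time", {
  m <- unit_square_mesh()
  m$fixed[2] <- TRUE
  F <- matrix(0, 4, 2); F[1, ] <- c(1, 0); F[2, ] <- c(5, 5)
  m2 <- euler_step(m, F, 0.001)
  expect_equal(m2$pos[1, ] - m$pos[1, ], c(0.001, 0))
  expect_equal(m2$pos[2, ], m$pos[2, ])
  expect_equal(m2$clock, m$clock + 0.001)
  F[3, 1] <- NaN
  expect_error(euler_step(m, F, 0.001), "instability|non-finite")
})

test_that("passive relaxation never increases the energy", {
  m <- random_voronoi_mesh(16, seed = 7)
  p <- energy_params(K = 1, gamma = 0.04, lambda = 0.12)
  e_prev <- total_energy(m, p)
  for (i in 1:1000) {
    m <- euler_step(m, vertex_forces(m, p), 0.001)
    if (i %% 100 == 0) {
      e <- total_energy(m, p)
      expect_lte(e, e_prev + 1e-10)
      e_prev <- e
    }
  }
})

test_that("the compiled substep equals the R force/Euler path", {
  m <- random_voronoi_mesh(14, seed = 11)
  m$type[1:3] <- c("endothelial_tip", "endothelial_stalk", "lumen")
  p <- energy_params(K = c(epithelial_central = 1, epithelial_peripheral = 1.2,
                           endothelial_tip = 3, endothelial_stalk = 3,
                           lumen = 0.8),
                     gamma = 0.05, lambda = default_lambda_table())
  m$fixed[5] <- TRUE
  fl <- thyromorph:::flatten_mesh(m, p, rearrangement_thresholds())
  out <- thyromorph:::vm_advance_cpp(
    m$pos, m$fixed, fl$cellptr, fl$ring, fl$typecode, m$A0, p$K, p$gamma,
    fl$ev1, fl$ev2, fl$elam, fl$exempt, fl$c_exempt,
    matrix(0, n_vertices(m), 2), matrix(0, 0, 5), fl$proj_ok,
    0.001, 1L, 0, -Inf)
  mr <- euler_step(m, vertex_forces(m, p), 0.001)
  expect_equal(out$pos, mr$pos, tolerance = 1e-12)
})
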