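test_that("peripheral/central classification matches the topology", {
  m <- classify_peripherality(honeycomb_flower())
  expect_equal(m$type[1], "epithelial_central")
  expect_equal(m$type[2:7], rep("epithelial_peripheral", 6))
  m2 <- classify_peripherality(two_cell_mesh())
  expect_true(all(m2$type == "epithelial_peripheral"))
})

test_that("classification agrees with a brute-force edge-sharing scan", {
  m <- random_voronoi_mesh(30, seed = 13)
  m <- classify_peripherality(m, endothelial_contact = FALSE)
  for (i in seq_len(n_cells(m))) {
    ring <- m$cells[[i]]
    n <- length(ring)
    has_unshared <- FALSE
    for (k in seq_len(n)) {
      a <- ring[k]; b <- ring[k %% n + 1L]
      shared <- any(vapply(seq_len(n_cells(m)), function(j) {
        if (j == i) return(FALSE)
        r <- m$cells[[j]]
        nn <- length(r)
        any(vapply(seq_len(nn), function(q)
          (r[q] == b && r[q %% nn + 1L] == a), logical(1)))
      }, logical(1)))
      if (!shared) { has_unshared <- TRUE; break }
    }
    expect_equal(m$type[i] == "epithelial_peripheral", has_unshared)
  }
})

test_that("endothelial contact promotes an interior cell to peripheral", {
  m <- honeycomb_flower()
  m$type[2] <- "endothelial_tip"
  m1 <- classify_peripherality(m, endothelial_contact = TRUE)
  expect_equal(m1$type[1], "epithelial_peripheral")   # touches the tip
  m0 <- classify_peripherality(m, endothelial_contact = FALSE)
  expect_equal(m0$type[1], "epithelial_central")
})

test_that("classification partitions the epithelium", {
  m <- random_voronoi_mesh(25, seed = 17)
  m$type[c(1, 4)] <- c("endothelial_tip", "lumen")
  m2 <- classify_peripherality(m)
  ep <- thyromorph:::is_epithelial(m2$type)
  expect_true(all(m2$type[ep] %in%
                    c("epithelial_central", "epithelial_peripheral")))
  expect_identical(m2$type[!ep], m$type[!ep])
})

test_that("cycle durations follow the measured baselines and the generation factor", {
  p <- proliferation_params()
  expect_equal(cycle_duration_at_birth("epithelial_peripheral", 0, p,
                                       jitter = FALSE), 11 + 20 / 60)
  expect_equal(cycle_duration_at_birth("epithelial_central", 0, p,
                                       jitter = FALSE), 31 + 52 / 60)
  p2 <- proliferation_params(generation_factor = 1.2)
  expect_equal(cycle_duration_at_birth("epithelial_peripheral", 2, p2,
                                       jitter = FALSE),
               (11 + 20 / 60) * 1.44, tolerance = 1e-12)
  expect_error(cycle_duration_at_birth("endothelial_tip", 0, p),
               "epithelial")
})

test_that("cells divide when their age reaches the cycle duration", {
  m <- classify_peripherality(honeycomb_flower())
  p <- proliferation_params(jitter_sd = 0)
  m$cycle_duration <- rep(10, 7)
  m$age <- rep(9.9995, 7)
  m$age[1] <- 1           # centre cell not due
  set.seed(1)
  res <- advance_cycles_and_divide(m, p, dt = 0.001)
  expect_equal(n_cells(res$mesh), 13)
  expect_equal(nrow(res$events), 6)
  # daughters restart the cycle one generation up
  d <- res$events$daughter
  expect_true(all(res$mesh$age[d] == 0))
  expect_true(all(res$mesh$generation[d] == 1L))
})

test_that("tip cells never divide; founder population doubles in one cycle", {
  m <- classify_peripherality(honeycomb_flower())
  m$type[2] <- "endothelial_tip"
  m$age <- rep(100, 7)
  m$cycle_duration <- rep(10, 7)
  p <- proliferation_params(jitter_sd = 0)
  set.seed(2)
  res <- advance_cycles_and_divide(m, p, dt = 0.001)
  expect_false(2 %in% res$events$cell)
  expect_false(any(res$events$cell_type == "endothelial_tip"))

  # n founders of equal duration, g = 1: exactly 2n cells just after T
  m2 <- random_voronoi_mesh(12, seed = 30)
  m2 <- classify_peripherality(m2)
  p2 <- proliferation_params(generation_factor = 1, jitter_sd = 0)
  m2$cycle_duration <- rep(5, 12)
  m2$age <- rep(0, 12)
  set.seed(3)
  for (k in 1:11) {
    res <- advance_cycles_and_divide(m2, p2, dt = 0.5)
    m2 <- res$mesh
  }
  expect_equal(n_cells(m2), 24)
})

test_that("elongated stalk cells divide by shape and relax their elongation", {
  m <- tissue_mesh(rbind(c(0, 0), c(3, 0), c(3, 1), c(0, 1)), list(1:4),
                   "endothelial_stalk")
  ep <- endothelial_params(elongation_threshold = 2)
  expect_gt(elongation_factor(m, 1), 2)
  res <- stalk_divide_if_elongated(m, ep)
  expect_equal(n_cells(res$mesh), 2)
  expect_true(all(res$mesh$type == "endothelial_stalk"))
  for (i in 1:2)
    expect_lt(elongation_factor(res$mesh, i), elongation_factor(m, 1))
  # a round stalk does not divide
  sq <- unit_square_mesh("endothelial_stalk")
  expect_equal(n_cells(stalk_divide_if_elongated(sq, ep)$mesh), 1)
})

test_that("branch addition extrudes a tip+stalk pair and respects the cutoff", {
  m <- random_voronoi_mesh(40, seed = 19)
  m <- classify_peripherality(m)
  ep <- endothelial_params()
  res <- add_endothelial_branch(m, ep, clock = 0)
  expect_true(res$added)
  m2 <- res$mesh
  expect_equal(sum(m2$type == "endothelial_tip"), 1)
  expect_equal(sum(m2$type == "endothelial_stalk"), 1)
  expect_equal(length(m2$boundaries), 1)
  expect_gt(sum(m2$fixed), 0)
  m2 <- rearrangement_sweep(m2)
  expect_valid_mesh(m2)
  # past the cutoff: no-op
  res2 <- add_endothelial_branch(m, ep, clock = 30)
  expect_false(res2$added)
  expect_identical(res2$mesh$cells, m$cells)
})

test_that("the EdU-proxy fraction tracks cells close to division", {
  m <- classify_peripherality(honeycomb_flower())
  p <- proliferation_params(edu_window = 0.5)
  m$cycle_duration <- rep(10, 7)
  m$age <- c(9.8, 9.7, rep(1, 5))   # two cells within 0.5 h of dividing
  pf <- proliferating_fraction(m, p)
  expect_equal(pf[["overall"]], 2 / 7)
})
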