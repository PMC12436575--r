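# Synthetic salt-leached porosity generator and structured meshing.

test_that("pore_spec enforces its invariants", {
  expect_s3_class(pore_spec(450), "pore_spec")
  expect_error(pore_spec(-100))
  expect_error(pore_spec(150, half_band = 200))   # diameters must stay > 0
  expect_error(pore_spec(450, target_porosity = 1))
})

test_that("same seed reproduces the identical realization and mesh labels", {
  a <- generate_porous_domain(pore_spec(450, 100, 0.6, rng_seed = 7))
  b <- generate_porous_domain(pore_spec(450, 100, 0.6, rng_seed = 7))
  expect_identical(a$pores, b$pores)
  expect_identical(a$achieved_porosity, b$achieved_porosity)
  ma <- mesh_domain(a, 0.1, include_bone = FALSE)
  mb <- mesh_domain(b, 0.1, include_bone = FALSE)
  expect_identical(ma$region, mb$region)
  c <- generate_porous_domain(pore_spec(450, 100, 0.6, rng_seed = 8))
  expect_false(identical(a$pores, c$pores))
})

test_that("achieved porosity lands within 0.02 of target for all bands", {
  for (mean_um in c(300, 450, 600)) {
    for (seed in 1:20) {
      d <- generate_porous_domain(
        pore_spec(mean_um, 100, 0.6, rng_seed = seed))
      expect_lt(abs(d$achieved_porosity - 0.6), 0.02 + 1e-12)
      expect_true(all(abs(d$pores$diameter - mean_um) <= 100))
      expect_true(all(d$pores$x^2 + d$pores$y^2 <= 4^2))
      expect_true(all(d$pores$x >= 0 & d$pores$y >= 0))
    }
  }
})

test_that("zero target porosity gives a fully solid anchor", {
  d <- generate_porous_domain(pore_spec(450, 100, 0, rng_seed = 1))
  expect_equal(nrow(d$pores), 0)
  m <- mesh_domain(d, 0.1, include_bone = FALSE)
  expect_true(all(m$region == "ANCHOR"))
})

test_that("an unreachable porosity target fails with a diagnostic", {
  # a single 0.9 mm pore covers most of a 0.5 mm anchor, so every insertion
  # overshoots the 0.3 target and is rejected until the attempt cap
  expect_error(
    generate_porous_domain(pore_spec(900, 0, 0.3, rng_seed = 1),
                           anchor_radius = 0.5, max_attempts = 200),
    "not reached")
})

test_that("mesh refuses element sizes that cannot resolve the pores", {
  d <- generate_porous_domain(pore_spec(300, 100, 0.3, rng_seed = 2),
                              anchor_radius = 2)
  expect_error(mesh_domain(d, 0.15), "unresolved")
  expect_s3_class(mesh_domain(d, 0.1), "fe_mesh")
})

test_that("mesh volume matches the analytic quarter-annulus volume", {
  d <- generate_porous_domain(pore_spec(450, 100, 0.6, rng_seed = 7))
  for (el in c("quad", "tri")) {
    m <- mesh_domain(d, 0.05, element = el, include_bone = TRUE)
    expect_lt(abs(sum(m$volume) / (pi * 5^2 / 4 * 2) - 1), 0.01)
    m2 <- mesh_domain(d, 0.05, element = el, include_bone = FALSE)
    expect_lt(abs(sum(m2$volume) / (pi * 4^2 / 4 * 2) - 1), 0.01)
  }
})

test_that("mesh porosity and interface area track the domain", {
  d <- generate_porous_domain(pore_spec(450, 100, 0.6, rng_seed = 7))
  m <- mesh_domain(d, 0.05, include_bone = FALSE)
  expect_lt(abs(mean(m$region == "VOID") - d$achieved_porosity), 0.02)
  # staircase projected area integrates to the cylinder area pi*R/2 * t
  expect_lt(abs(m$interface$area / (pi * 4 / 2 * 2) - 1), 0.01)
})

test_that("adjacency matches a brute-force shared-edge search", {
  for (el in c("tri", "quad")) {
    m <- rect_mesh(2, 2, h = 1, element = el)
    expect_identical(build_adjacency(m), brute_adjacency(m))
    expect_identical(m$adjacency, brute_adjacency(m))
  }
  d <- generate_porous_domain(pore_spec(600, 100, 0.4, rng_seed = 5),
                              anchor_radius = 1.5)
  m <- mesh_domain(d, 0.1, include_bone = FALSE, element = "tri")
  expect_identical(m$adjacency, brute_adjacency(m))
})

test_that("adjacency is symmetric and irreflexive on generated meshes", {
  m <- small_porous_mesh(seed = 9)
  adj <- m$adjacency
  for (i in seq_along(adj)) {
    expect_false(i %in% adj[[i]])
    for (j in adj[[i]]) expect_true(i %in% adj[[j]])
  }
  m1 <- rect_mesh(1, 1, element = "quad")   # single element: no neighbors
  expect_identical(m1$adjacency, list(integer(0)))
})

test_that("pore islands are exactly the void components cut off from the interface", {
  dom <- island_domain()
  m <- mesh_domain(dom, 0.1, include_bone = FALSE)
  isl <- find_pore_islands(m)
  expect_equal(length(isl), 1)
  # the island is the interior pore at (0.8, 0.8)
  cc <- m$centroid[isl[[1]], , drop = FALSE]
  expect_true(all(sqrt((cc[, 1] - 0.8)^2 + (cc[, 2] - 0.8)^2) <= 0.35))
  # oracle: islands = void elements not reachable from throats by BFS
  reach <- brute_reachable_void(m)
  expect_setequal(sort(unlist(isl)),
                  setdiff(which(m$region == "VOID"), reach))
  # solid anchor: no voids, no islands
  solid <- generate_porous_domain(pore_spec(450, 100, 0, rng_seed = 1),
                                  anchor_radius = 2)
  expect_identical(find_pore_islands(mesh_domain(solid, 0.1,
                                                 include_bone = FALSE)),
                   list())
})

test_that("3D voxel meshing reproduces the study-scale element counts", {
  d3 <- generate_porous_domain(pore_spec(300, 100, 0.6, rng_seed = 3),
                               dim = 3)
  expect_lt(abs(d3$achieved_porosity - 0.6), 0.02 + 1e-12)
  m3 <- mesh_domain(d3, 0.05, include_bone = FALSE)
  # quarter slice volume pi R^2 t / 4 within 1%
  expect_lt(abs(sum(m3$volume) / (pi * 16 / 4 * 2) - 1), 0.01)
  # on the order of 2e5 elements; void-region count in the 1.1e5 - 1.3e5 band
  expect_gt(nrow(m3$elems), 1.5e5)
  expect_lt(nrow(m3$elems), 4e5)
  nvoid <- sum(m3$region == "VOID")
  expect_gt(nvoid, 1.0e5)
  expect_lt(nvoid, 1.4e5)
  # voxel face adjacency: symmetric, irreflexive (spot check)
  idx <- seq(1, nrow(m3$elems), length.out = 500)
  for (i in as.integer(idx)) {
    expect_false(i %in% m3$adjacency[[i]])
    for (j in m3$adjacency[[i]]) expect_true(i %in% m3$adjacency[[j]])
  }
})
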