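# Osteoconnectivity-gated remodeling: stimulus, Euler rule, gate, loop.

test_that("stimulus is energy density per unit apparent density", {
  mk <- function(U, rho) {
    sol <- structure(list(stress = NULL, strain_mech = NULL), class = "fe_solution")
    # build a solution whose SED evaluates to U exactly: uniaxial with nu=0
    sol$stress <- cbind(sx = sqrt(2 * U), sy = 0 * U, sz = 0 * U, txy = 0 * U)
    sol$strain_mech <- cbind(ex = sqrt(2 * U), ey = 0 * U, ez = 0 * U,
                             gxy = 0 * U)
    mat <- structure(list(rho = rho), class = "material_state")
    compute_stimulus(sol, mat)
  }
  expect_equal(mk(0.004, 1.0), 0.004)           # equals k at bone density
  expect_equal(mk(0.0008, 0.2), 0.004)
  expect_equal(mk(0, 0.5), 0)
  expect_equal(mk(0.004, 0.001), 0.004 / 0.01)  # density clamped at floor
})

test_that("Euler update reproduces the three-branch rule by hand", {
  p <- remodeling_params()      # B = 1, k = 0.004, delta = 0.1, dt = 0.01
  # apposition branch
  expect_equal(euler_update(0.01, 0.0050, p),
               0.01 + 0.01 * (0.0050 - 0.0044), tolerance = 1e-15)
  expect_equal(euler_update(0.01, 0.0050, p), 0.010006)
  # lazy zone: no change anywhere in (0.0036, 0.0044)
  for (S in c(0.0037, 0.0040, 0.0042, 0.00439))
    expect_identical(euler_update(0.2, S, p), 0.2)
  # resorption branch clamps at the lower bound
  expect_equal(euler_update(0.01, 0.0010, p), 0.01)
  expect_equal(euler_update(0.5, 0.0010, p),
               0.5 + 0.01 * (0.0010 - 0.0036))
  # upper bound clamp
  expect_equal(euler_update(1.69999, 10, p), 1.7)
  # vectorized over elements
  expect_equal(euler_update(c(0.01, 0.2, 1.7), c(0.005, 0.004, 10), p),
               c(0.010006, 0.2, 1.7))
})

test_that("density-to-modulus law honors both anchor points", {
  expect_equal(density_to_modulus(0.01), 0.05, tolerance = 1e-9)
  expect_equal(density_to_modulus(0.8), 1940.48, tolerance = 1e-9)
  # gamma = log(1940.48/0.05)/log(0.8/0.01) = 2.4113...; E(0.4) ~ 364.6 MPa
  gam <- log(1940.48 / 0.05) / log(0.8 / 0.01)
  expect_equal(gam, 2.41132, tolerance = 1e-5)
  expect_equal(density_to_modulus(0.4), 1940.48 * 0.5^gam, tolerance = 1e-9)
  expect_equal(density_to_modulus(0.4), 364.6, tolerance = 0.5)
  expect_equal(density_to_modulus(0.005), 0.05)   # floored
})

test_that("the gate opens exactly as the toy element network prescribes", {
  adj <- toy_adjacency()
  rho0 <- rep(0.01, 5)
  p1 <- remodeling_params(alpha_gate = 1.0)
  # iteration 1: only interface-adjacent void elements (here: element 1)
  e1 <- gate_eligibility(1, adj, rho0, rho0, interface_elements = 1L,
                         void_elements = 1:5, p1)
  expect_identical(which(e1), 1L)
  # element 1 grows; with the relaxed gate its neighbors 2, 3, 4 open up
  rho <- rho0; rho[1] <- 0.012
  e2 <- gate_eligibility(2, adj, rho, rho0, 1L, 1:5, p1, eligible = e1)
  expect_identical(which(e2), c(1L, 2L, 3L, 4L))
  # element 3 is connected to 1, 2, 5: raising rho_5 also qualifies it
  rho_b <- rho0; rho_b[5] <- 0.02
  e2b <- gate_eligibility(2, adj, rho_b, rho0, 1L, 1:5, p1, eligible = e1)
  expect_true(e2b[3])
  # strict gate at 25%: a neighbor at 1.2 x initial does NOT open the gate
  p125 <- remodeling_params(alpha_gate = 1.25)
  rho_c <- rho0; rho_c[1] <- 0.012
  e2c <- gate_eligibility(2, adj, rho_c, rho0, 1L, 1:5, p125, eligible = e1)
  expect_identical(which(e2c), 1L)
  # ... but 1.3 x initial does
  rho_d <- rho0; rho_d[1] <- 0.013
  e2d <- gate_eligibility(2, adj, rho_d, rho0, 1L, 1:5, p125, eligible = e1)
  expect_identical(which(e2d), c(1L, 2L, 3L, 4L))
  # an element with no interface contact is never eligible at iteration 1
  expect_false(gate_eligibility(1, adj, rho0, rho0, 1L, 1:5, p1)[5])
  # eligibility is permanent
  e3 <- gate_eligibility(3, adj, rho0, rho0, 1L, 1:5, p1, eligible = e2)
  expect_true(all(e3[which(e2)]))
})

test_that("zero load produces zero growth and immediate homeostasis", {
  m <- small_porous_mesh(seed = 3)
  h <- run_ingrowth(m, material_state(m), 0,
                    remodeling_params(max_iterations = 10))
  expect_lt(nrow(h$metrics), 10)          # stopped early
  expect_true(h$converged)
  expect_equal(h$metrics$grown_element_count[nrow(h$metrics)], 0)
  expect_identical(h$rho, h$rho_init)
  met <- ingrowth_metrics(h, m)
  expect_equal(met$depth_mm, 0)
  expect_equal(met$added_mass_g, 0)
  expect_equal(met$filled_volume_ratio, 0)
})

test_that("the front advances at most one adjacency layer per iteration", {
  m <- small_porous_mesh(seed = 3)
  n_it <- 8
  h <- run_ingrowth(m, material_state(m), 22,
                    remodeling_params(alpha_gate = 1,
                                      max_iterations = n_it),
                    record_densities = TRUE)
  # BFS layer index of every void element from the interface throats
  void <- which(m$region == "VOID")
  layer <- rep(NA_integer_, nrow(m$elems))
  frontier <- intersect(m$interface$elements, void)
  layer[frontier] <- 1L
  l <- 1L
  while (length(frontier) > 0) {
    nxt <- unique(unlist(m$adjacency[frontier]))
    nxt <- nxt[is.na(layer[nxt]) & m$region[nxt] == "VOID"]
    layer[nxt] <- l + 1L
    frontier <- nxt
    l <- l + 1L
  }
  for (i in seq_len(nrow(h$metrics))) {
    grown <- which(h$densities[[i]] > h$rho_init + 1e-12)
    expect_true(all(layer[grown] <= i))
    # depth bound: i layers of at most one element diagonal each
    expect_lte(h$metrics$ingrowth_depth_mm[i], i * m$h * sqrt(2))
  }
  # grown element count never decreases
  expect_true(all(diff(h$metrics$grown_element_count) >= 0))
  # densities stay in bounds throughout
  for (i in seq_len(nrow(h$metrics)))
    expect_true(all(h$densities[[i]] >= 0.01 - 1e-12 &
                      h$densities[[i]] <= 1.7 + 1e-12))
})

test_that("a stricter gate never grows more than a relaxed one", {
  m <- small_porous_mesh(seed = 6)
  mat <- material_state(m)
  hs <- lapply(c(1, 1.25, 1.5), function(a)
    run_ingrowth(m, mat, 22,
                 remodeling_params(alpha_gate = a, max_iterations = 10),
                 record_densities = TRUE))
  for (i in 1:10) {
    g1 <- which(hs[[1]]$densities[[i]] > hs[[1]]$rho_init + 1e-12)
    g2 <- which(hs[[2]]$densities[[i]] > hs[[2]]$rho_init + 1e-12)
    g3 <- which(hs[[3]]$densities[[i]] > hs[[3]]$rho_init + 1e-12)
    expect_true(all(g3 %in% g2))
    expect_true(all(g2 %in% g1))
  }
})

test_that("grown bone stays connected to the interface (no free nucleation)", {
  m <- small_porous_mesh(seed = 3)
  h <- run_ingrowth(m, material_state(m), 22,
                    remodeling_params(max_iterations = 12))
  grown <- which(h$rho > h$rho_init + 1e-12)
  seed <- intersect(m$interface$elements, grown)
  expect_gt(length(seed), 0)
  seen <- rep(FALSE, nrow(m$elems)); seen[seed] <- TRUE
  frontier <- seed
  while (length(frontier) > 0) {
    nxt <- unique(unlist(m$adjacency[frontier]))
    nxt <- nxt[!seen[nxt] & nxt %in% grown]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  expect_true(all(seen[grown]))
})

test_that("pore islands never capture ingrowth", {
  dom <- island_domain()
  m <- mesh_domain(dom, 0.1, include_bone = FALSE)
  isl <- find_pore_islands(m)
  expect_equal(length(isl), 1)
  h <- run_ingrowth(m, material_state(m), 22,
                    remodeling_params(max_iterations = 15))
  island_elems <- unlist(isl)
  expect_identical(h$rho[island_elems], h$rho_init[island_elems])
  # while the open pore did grow
  expect_gt(h$metrics$grown_element_count[nrow(h$metrics)], 0)
})

test_that("ingrowth metrics follow their definitions", {
  # two-element toy: one void element densified from 0.01 to 0.8
  m <- rect_mesh(2, 1, h = 0.5, thickness = 2)
  m$region <- c("ANCHOR", "VOID")
  hist <- structure(list(
    rho = c(1.19, 0.8), rho_init = c(1.19, 0.01),
    params = remodeling_params()), class = "ingrowth_history")
  met <- ingrowth_metrics(hist, m)
  V <- 0.5 * 0.5 * 2                       # mm^3
  expect_equal(met$added_mass_g, 0.79 * V * 1e-3)
  expect_equal(met$grown_count, 1)
  expect_equal(met$filled_volume_ratio, 1)  # the only void element is filled
  hist$rho <- c(1.19, 0.2)                  # grown but below fill threshold
  met2 <- ingrowth_metrics(hist, m)
  expect_equal(met2$filled_volume_ratio, 0)
  expect_equal(met2$grown_count, 1)
})
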