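# Plane-strain FE core: patch tests, energy identities, analytic benchmarks.

test_that("uniaxial pressure patch test is exact for quads and triangles", {
  for (el in c("quad", "tri")) {
    m <- rect_mesh(4, 3, h = 0.5, element = el)
    mat <- material_state(m, anchor_E = 1000, anchor_nu = 0)
    bf <- m$boundary$faces
    lc <- load_case(pressure = list(faces = bf[bf$set == "ymax", ], p = 2),
                    bcs = rbind(bc_fix(m$boundary$sym_x_nodes, 2L),
                                bc_fix(m$boundary$sym_y_nodes, 1L)))
    sol <- assemble_and_solve(m, mat, lc)
    expect_lt(max(abs(sol$stress[, "sy"] + 2)), 1e-10)
    expect_lt(max(abs(sol$stress[, "sx"])), 1e-10)
    expect_lt(max(abs(sol$strain[, "ey"] + 2 / 1000)), 1e-13)
    # U = sigma^2 / (2E)
    expect_lt(max(abs(sol$sed - 2^2 / (2 * 1000))), 1e-12)
  }
})

test_that("in-plane free swelling is stress-free with displacement eps0 * x", {
  m <- rect_mesh(3, 3, h = 1, element = "quad")
  mat <- material_state(m, anchor_E = 433, anchor_nu = 0.25)
  e0 <- matrix(0, nrow(m$elems), 4)
  e0[, 1] <- 0.05; e0[, 2] <- 0.05          # in-plane swelling
  lc <- load_case(eigenstrain = e0,
                  bcs = rbind(bc_fix(m$boundary$sym_x_nodes, 2L),
                              bc_fix(m$boundary$sym_y_nodes, 1L)))
  sol <- assemble_and_solve(m, mat, lc)
  expect_lt(max(abs(sol$stress)), 1e-9)
  expect_lt(max(abs(sol$sed)), 1e-12)
  expect_lt(max(abs(sol$u[, 1] - 0.05 * m$nodes[, 1])), 1e-12)
  expect_lt(max(abs(sol$u[, 2] - 0.05 * m$nodes[, 2])), 1e-12)
})

test_that("fully confined isotropic eigenstrain gives the closed-form hydrostat", {
  # sigma = -E eps0 / (1 - 2 nu) = -74.5 MPa for the wet 85/15 co-polymer
  m <- rect_mesh(3, 2, h = 0.5)
  mat <- material_state(m, anchor_E = 433, anchor_nu = 0.25)
  eps0 <- 0.9920 * 0.08672                   # = 0.0860262 (hand-checked)
  expect_equal(eps0, 0.08602624, tolerance = 1e-8)
  alln <- seq_len(nrow(m$nodes))
  sol <- assemble_and_solve(
    m, mat,
    load_case(eigenstrain = eigenstrain_iso(m, eps0,
                                            seq_len(nrow(m$elems))),
              bcs = rbind(bc_fix(alln, 1L), bc_fix(alln, 2L))))
  expected <- -433 * eps0 / (1 - 2 * 0.25)
  expect_equal(expected, -74.5, tolerance = 1e-4)
  for (comp in c("sx", "sy", "sz"))
    expect_equal(unname(sol$stress[, comp]),
                 rep(expected, nrow(m$elems)), tolerance = 1e-9)
})

test_that("strain energy density matches closed forms in shear", {
  # pure shear tau = G * gamma imposed through affine boundary displacement
  m <- rect_mesh(3, 3, h = 1)
  E <- 900; nu <- 0; G <- E / (2 * (1 + nu))
  mat <- material_state(m, anchor_E = E, anchor_nu = nu)
  gam <- 0.002
  alln <- seq_len(nrow(m$nodes))
  sol <- assemble_and_solve(
    m, mat,
    load_case(bcs = rbind(bc_fix(alln, 1L, gam * m$nodes[, 2]),
                          bc_fix(alln, 2L, 0))))
  tau <- G * gam
  expect_lt(max(abs(sol$stress[, "txy"] - tau)), 1e-10)
  expect_lt(max(abs(sol$sed - tau^2 / (2 * G))), 1e-13)
  # zero strain -> zero energy
  sol0 <- assemble_and_solve(m, mat,
                             load_case(bcs = rbind(bc_fix(alln, 1L),
                                                   bc_fix(alln, 2L))))
  expect_equal(max(abs(element_sed(sol0))), 0)
})

test_that("external work balances stored energy on a heterogeneous mesh", {
  m <- small_porous_mesh(seed = 4)
  mat <- material_state(m)
  fa <- m$interface$faces
  fa <- fa[m$region[fa$elem] == "ANCHOR", ]
  sol <- assemble_and_solve(m, mat,
                            load_case(pressure = list(faces = fa, p = 5),
                                      bcs = bc_symmetry(m)))
  stored <- sum(sol$sed * m$volume)
  expect_lt(abs(sol$ext_work - stored) / stored, 1e-8)
})

test_that("pressurized annulus converges to the Lame solution under refinement", {
  # quarter ring, inner radius 2 (pore), outer radius 4, inner pressure p
  p <- 10; a <- 2; b <- 4; E <- 500; nu <- 0.3
  u_lame <- function(r) {
    A <- p * a^2 / (b^2 - a^2)
    B <- p * a^2 * b^2 / (b^2 - a^2)
    (1 + nu) / E * ((1 - 2 * nu) * A * r + B / r)
  }
  err <- sapply(c(0.2, 0.1), function(h) {
    dom <- generate_porous_domain(
      pore_spec(2 * a * 1000, 0, 0.2, rng_seed = 1),
      anchor_radius = b,
      pores = data.frame(x = 0, y = 0, diameter = 2 * a * 1000))
    m <- mesh_domain(dom, h, include_bone = FALSE, keep_void = FALSE)
    mat <- material_state(m, anchor_E = E, anchor_nu = nu)
    bf <- m$boundary$faces
    inner <- bf[bf$set == "inner", ]
    sol <- assemble_and_solve(m, mat,
                              load_case(pressure = list(faces = inner, p = p),
                                        bcs = bc_symmetry(m)))
    outer_nodes <- unique(c(bf$n1[bf$set == "interface"],
                            bf$n2[bf$set == "interface"]))
    ur <- sqrt(sol$u[outer_nodes, 1]^2 + sol$u[outer_nodes, 2]^2)
    rn <- sqrt(m$nodes[outer_nodes, 1]^2 + m$nodes[outer_nodes, 2]^2)
    mean(abs(ur - u_lame(rn)))
  })
  expect_lt(err[2], err[1])              # refinement reduces the error
  expect_lt(err[2] / u_lame(b), 0.05)    # and lands near the analytic value
})

test_that("solver rejects unconstrained and 3D systems", {
  m <- rect_mesh(2, 2)
  mat <- material_state(m, anchor_E = 100, anchor_nu = 0)
  expect_error(assemble_and_solve(m, mat, load_case(bcs = NULL)),
               "singular")
  d3 <- generate_porous_domain(pore_spec(450, 100, 0, rng_seed = 1),
                               anchor_radius = 1, slice_thickness = 0.5,
                               dim = 3)
  m3 <- mesh_domain(d3, 0.25, include_bone = FALSE)
  expect_error(assemble_and_solve(m3, material_state(m3), load_case()),
               "2D")
})
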