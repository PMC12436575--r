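# Small-strain linear-elastic plane-strain FE core on structured meshes.
# Units: mm - MPa - g/cm^3. Forces are N (MPa * mm^2), energy densities are
# J/cm^3 (numerically identical to MPa), so stimulus U/rho is J/g directly.

#' Per-element material state
#'
#' Elastic modulus, Poisson ratio and apparent density per element,
#' initialized from region defaults: wet anchor co-polymer, low-stiffness
#' dummy material in the voids (so pores can be analyzed before ingrowth with
#' negligible influence), and trabecular bone.
#'
#' @param mesh An `fe_mesh`.
#' @param anchor_E,anchor_nu Anchor co-polymer modulus (MPa) / Poisson ratio.
#' @param void_E,void_nu,void_rho Dummy (pre-ingrowth void) properties;
#'   `void_rho` is the initial apparent density (g/cm^3) of the void
#'   elements, equal to the remodeling lower bound.
#' @param bone_E,bone_nu,bone_rho Bone properties.
#' @param anchor_rho Nominal co-polymer density, g/cm^3 (bookkeeping only;
#'   the anchor matrix does not remodel).
#' @return An object of class `material_state` with vectors `E`, `nu`, `rho`.
#' @export
material_state <- function(mesh, anchor_E = 433, anchor_nu = 0.25,
                           void_E = 0.05, void_nu = 0.3, void_rho = 0.01,
                           bone_E = 1940.48, bone_nu = 0.34, bone_rho = 0.8,
                           anchor_rho = 1.19) {
  stopifnot(inherits(mesh, "fe_mesh"))
  nel <- nrow(mesh$elems)
  E <- numeric(nel); nu <- numeric(nel); rho <- numeric(nel)
  a <- mesh$region == "ANCHOR"; v <- mesh$region == "VOID"
  b <- mesh$region == "BONE"
  E[a] <- anchor_E; E[v] <- void_E; E[b] <- bone_E
  nu[a] <- anchor_nu; nu[v] <- void_nu; nu[b] <- bone_nu
  rho[a] <- anchor_rho; rho[v] <- void_rho; rho[b] <- bone_rho
  stopifnot(all(E > 0))
  structure(list(E = E, nu = nu, rho = rho), class = "material_state")
}

#' Assemble a load case
#'
#' @param pressure A list `list(faces = <face table>, p = <MPa>)` or a list
#'   of such entries. Pressure acts against the outward face normal
#'   (compressive for positive `p`).
#' @param eigenstrain `NULL`, or an `nel x 4` matrix of stress-free strains
#'   `(e_xx, e_yy, e_zz, gamma_xy)` per element (see [eigenstrain_iso()]).
#' @param bcs Data frame of prescribed displacements with columns `node`,
#'   `dof` (1 = x, 2 = y) and `value` (mm); see [bc_symmetry()], [bc_fix()].
#' @param nodal_forces Optional data frame `node`, `dof`, `value` (N).
#' @return An object of class `load_case`.
#' @export
load_case <- function(pressure = NULL, eigenstrain = NULL, bcs = NULL,
                      nodal_forces = NULL) {
  if (!is.null(pressure) && !is.null(pressure$faces))
    pressure <- list(pressure)
  structure(list(pressure = pressure, eigenstrain = eigenstrain,
                 bcs = bcs, nodal_forces = nodal_forces),
            class = "load_case")
}

#' @rdname load_case
#' @param nodes Integer node ids.
#' @param dof 1 (x) or 2 (y).
#' @param value Prescribed displacement, mm.
#' @export
bc_fix <- function(nodes, dof, value = 0) {
  data.frame(node = nodes, dof = dof, value = value)
}

#' @rdname load_case
#' @param mesh An `fe_mesh`; returns the quarter-slice symmetry conditions
#'   (u_y = 0 on y = 0, u_x = 0 on x = 0).
#' @export
bc_symmetry <- function(mesh) {
  rbind(bc_fix(mesh$boundary$sym_x_nodes, 2L),
        bc_fix(mesh$boundary$sym_y_nodes, 1L))
}

#' Isotropic (hygroscopic) eigenstrain field
#'
#' @param mesh An `fe_mesh`.
#' @param value Scalar stress-free normal strain.
#' @param elements Elements carrying the eigenstrain (default: ANCHOR).
#' @return An `nel x 4` eigenstrain matrix for [load_case()].
#' @export
eigenstrain_iso <- function(mesh, value,
                            elements = which(mesh$region == "ANCHOR")) {
  e0 <- matrix(0, nrow(mesh$elems), 4)
  e0[elements, 1:3] <- value
  e0
}

# ---- element matrices -------------------------------------------------------

.dmat_plane_strain <- function(E, nu) {
  c1 <- E / ((1 + nu) * (1 - 2 * nu))
  matrix(c(c1 * (1 - nu), c1 * nu, 0,
           c1 * nu, c1 * (1 - nu), 0,
           0, 0, c1 * (1 - 2 * nu) / 2), 3, 3)
}

# unit-modulus stiffness of the square Q4 element (size-independent)
.q4_khat <- function(nu) {
  gp <- c(-1, 1) / sqrt(3)
  xi_i <- c(-1, 1, 1, -1); eta_i <- c(-1, -1, 1, 1)
  D <- .dmat_plane_strain(1, nu)
  K <- matrix(0, 8, 8)
  for (xi in gp) for (eta in gp) {
    dNdx <- 0.25 * xi_i * (1 + eta * eta_i)   # reference coords, J = I
    dNdy <- 0.25 * eta_i * (1 + xi * xi_i)
    B <- matrix(0, 3, 8)
    B[1, seq(1, 8, 2)] <- dNdx
    B[2, seq(2, 8, 2)] <- dNdy
    B[3, seq(1, 8, 2)] <- dNdy
    B[3, seq(2, 8, 2)] <- dNdx
    K <- K + t(B) %*% D %*% B
  }
  K
}

# centroid strain-displacement operator for the square Q4 of side h
.q4_bbar <- function(h) {
  xi_i <- c(-1, 1, 1, -1); eta_i <- c(-1, -1, 1, 1)
  dNdx <- xi_i / (2 * h); dNdy <- eta_i / (2 * h)
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNdx
  B[2, seq(2, 8, 2)] <- dNdy
  B[3, seq(1, 8, 2)] <- dNdy
  B[3, seq(2, 8, 2)] <- dNdx
  B
}

.elem_dofs <- function(elems) {
  npe <- ncol(elems)
  ed <- matrix(0L, nrow(elems), 2L * npe)
  for (a in seq_len(npe)) {
    ed[, 2L * a - 1L] <- 2L * elems[, a] - 1L
    ed[, 2L * a] <- 2L * elems[, a]
  }
  ed
}

# per-element in-plane eigen-stress (sx, sy, txy) from eigenstrain rows
.eigen_stress_ip <- function(E, nu, e0) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  tr <- e0[, 1] + e0[, 2] + e0[, 3]
  cbind(lam * tr + 2 * mu * e0[, 1],
        lam * tr + 2 * mu * e0[, 2],
        mu * e0[, 4])
}

.tri_geom <- function(mesh) {
  el <- mesh$elems
  x <- matrix(mesh$nodes[el, 1], ncol = 3)
  y <- matrix(mesh$nodes[el, 2], ncol = 3)
  b1 <- y[, 2] - y[, 3]; b2 <- y[, 3] - y[, 1]; b3 <- y[, 1] - y[, 2]
  c1 <- x[, 3] - x[, 2]; c2 <- x[, 1] - x[, 3]; c3 <- x[, 2] - x[, 1]
  A <- 0.5 * (b3 * c2 - b2 * c3)
  list(b = cbind(b1, b2, b3), c = cbind(c1, c2, c3), A = A)
}

#' Assemble and solve the linear elastostatic system
#'
#' Plane-strain FE solve with pressure, nodal and eigenstrain loading and
#' prescribed displacements. Returns the displacement field and per-element
#' centroid stress, strain and strain energy density. Stress is computed with
#' the eigenstrain subtracted (`sigma = C (eps - eps0)`), and the strain
#' energy density uses the mechanical strain conjugate to that stress,
#' `U = sigma : (eps - eps0) / 2`, in J/cm^3.
#'
#' @param mesh A 2D `fe_mesh`.
#' @param mat A `material_state`.
#' @param load A `load_case`. At least enough displacement constraints to
#'   remove rigid-body modes are required.
#' @param sed_strain `"mechanical"` (default) or `"total"`: which strain is
#'   used in the strain-energy-density product.
#' @return An object of class `fe_solution` with fields `u` (n x 2, mm),
#'   `stress` (nel x 4: sx, sy, sz, txy, MPa), `strain` (nel x 3 total
#'   in-plane), `strain_mech` (nel x 4), `sed` (J/cm^3), `reactions`
#'   (ndof, N) and `ext_work` (N mm).
#' @export
assemble_and_solve <- function(mesh, mat, load,
                               sed_strain = c("mechanical", "total")) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(mat, "material_state"),
            inherits(load, "load_case"))
  sed_strain <- match.arg(sed_strain)
  if (mesh$dim != 2)
    stop("the FE solver is 2D plane-strain; 3D meshes are geometry-only")
  nel <- nrow(mesh$elems)
  ndof <- 2L * nrow(mesh$nodes)
  thick <- mesh$thickness
  ed <- .elem_dofs(mesh$elems)

  nus <- sort(unique(mat$nu))
  nu_idx <- match(mat$nu, nus)

  if (mesh$elem_type == "quad") {
    khats <- vapply(nus, function(nu) as.vector(.q4_khat(nu)),
                    numeric(64))                    # 64 x n_nu
    vals <- khats[, nu_idx, drop = FALSE] *
      rep(mat$E * thick, each = 64)
    ii <- t(ed[, rep(1:8, times = 8), drop = FALSE])
    jj <- t(ed[, rep(1:8, each = 8), drop = FALSE])
  } else if (mesh$elem_type == "tri") {
    tg <- .tri_geom(mesh)
    sig <- paste(signif(tg$b[, 1] / sqrt(abs(tg$A)), 8),
                 signif(tg$b[, 2] / sqrt(abs(tg$A)), 8),
                 signif(tg$c[, 1] / sqrt(abs(tg$A)), 8),
                 signif(tg$c[, 2] / sqrt(abs(tg$A)), 8), nu_idx)
    grp <- match(sig, unique(sig))
    kgrp <- matrix(0, 36, max(grp))
    for (g in seq_len(max(grp))) {
      e <- which(grp == g)[1]
      B <- matrix(0, 3, 6)
      B[1, c(1, 3, 5)] <- tg$b[e, ]
      B[2, c(2, 4, 6)] <- tg$c[e, ]
      B[3, c(1, 3, 5)] <- tg$c[e, ]
      B[3, c(2, 4, 6)] <- tg$b[e, ]
      B <- B / (2 * tg$A[e])
      D <- .dmat_plane_strain(1, mat$nu[e])
      kgrp[, g] <- as.vector(t(B) %*% D %*% B * tg$A[e])
    }
    vals <- kgrp[, grp, drop = FALSE] * rep(mat$E * thick, each = 36)
    ii <- t(ed[, rep(1:6, times = 6), drop = FALSE])
    jj <- t(ed[, rep(1:6, each = 6), drop = FALSE])
  } else stop("unsupported element type for the solver: ", mesh$elem_type)

  K <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(vals), dims = c(ndof, ndof))

  f <- numeric(ndof)
  for (pr in load$pressure %||% list()) {
    fc <- pr$faces
    fx <- -pr$p * fc$nx * fc$len * thick / 2
    fy <- -pr$p * fc$ny * fc$len * thick / 2
    idx <- c(2L * fc$n1 - 1L, 2L * fc$n2 - 1L, 2L * fc$n1, 2L * fc$n2)
    add <- c(fx, fx, fy, fy)
    acc <- rowsum(add, idx)
    f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc[, 1]
  }
  if (!is.null(load$nodal_forces)) {
    nf <- load$nodal_forces
    idx <- 2L * (nf$node - 1L) + nf$dof
    acc <- rowsum(nf$value, idx)
    f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc[, 1]
  }
  e0 <- load$eigenstrain
  if (!is.null(e0)) {
    stopifnot(nrow(e0) == nel, ncol(e0) == 4)
    s0 <- .eigen_stress_ip(mat$E, mat$nu, e0)
    if (mesh$elem_type == "quad") {
      fe <- thick * mesh$h^2 * (t(.q4_bbar(mesh$h)) %*% t(s0))  # 8 x nel
    } else {
      tg <- .tri_geom(mesh)
      fe <- matrix(0, 6, nel)
      fe[1, ] <- tg$b[, 1] * s0[, 1] + tg$c[, 1] * s0[, 3]
      fe[2, ] <- tg$c[, 1] * s0[, 2] + tg$b[, 1] * s0[, 3]
      fe[3, ] <- tg$b[, 2] * s0[, 1] + tg$c[, 2] * s0[, 3]
      fe[4, ] <- tg$c[, 2] * s0[, 2] + tg$b[, 2] * s0[, 3]
      fe[5, ] <- tg$b[, 3] * s0[, 1] + tg$c[, 3] * s0[, 3]
      fe[6, ] <- tg$c[, 3] * s0[, 2] + tg$b[, 3] * s0[, 3]
      fe <- fe * rep(thick / 2, each = 6)
    }
    acc <- rowsum(as.vector(fe), as.vector(t(ed)))
    f[as.integer(rownames(acc))] <- f[as.integer(rownames(acc))] + acc[, 1]
  }

  u <- numeric(ndof)
  pd <- integer(0)
  if (!is.null(load$bcs) && nrow(load$bcs) > 0) {
    bdof <- 2L * (load$bcs$node - 1L) + load$bcs$dof
    keep <- !duplicated(bdof)
    pd <- bdof[keep]
    u[pd] <- load$bcs$value[keep]
  }
  if (length(pd) == 0) stop("singular system: no displacement constraints")
  free <- setdiff(seq_len(ndof), pd)
  rhs <- f[free] - as.vector(K[free, pd, drop = FALSE] %*% u[pd])
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  uf <- tryCatch(as.vector(Matrix::solve(Kff, rhs)),
                 error = function(e) stop("singular system after boundary ",
                                          "conditions: ", conditionMessage(e)))
  if (!all(is.finite(uf))) stop("non-finite FE solution (ill-conditioned?)")
  u[free] <- uf
  reactions <- as.vector(K %*% u) - f

  sol <- .recover_fields(mesh, mat, u, e0, sed_strain)
  sol$reactions <- reactions
  sol$ext_work <- 0.5 * sum(f[free] * u[free])
  sol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.recover_fields <- function(mesh, mat, u, e0, sed_strain) {
  nel <- nrow(mesh$elems)
  if (is.null(e0)) e0 <- matrix(0, nel, 4)
  ux <- u[seq(1, length(u), 2)]
  uy <- u[seq(2, length(u), 2)]
  el <- mesh$elems
  gp_strains <- NULL
  if (mesh$elem_type == "quad") {
    h <- mesh$h
    xi_i <- c(-1, 1, 1, -1); eta_i <- c(-1, -1, 1, 1)
    # centroid strains (reported) ...
    ex <- ey <- gxy <- numeric(nel)
    for (a in 1:4) {
      ex <- ex + xi_i[a] / (2 * h) * ux[el[, a]]
      ey <- ey + eta_i[a] / (2 * h) * uy[el[, a]]
      gxy <- gxy + eta_i[a] / (2 * h) * ux[el[, a]] +
        xi_i[a] / (2 * h) * uy[el[, a]]
    }
    # ... and 2x2 Gauss-point strains so element energy matches assembly
    g <- 1 / sqrt(3)
    gp_strains <- lapply(list(c(-g, -g), c(g, -g), c(g, g), c(-g, g)),
                         function(pt) {
      dNdx <- xi_i * (1 + pt[2] * eta_i) / (2 * h)
      dNdy <- eta_i * (1 + pt[1] * xi_i) / (2 * h)
      exg <- eyg <- gg <- numeric(nel)
      for (a in 1:4) {
        exg <- exg + dNdx[a] * ux[el[, a]]
        eyg <- eyg + dNdy[a] * uy[el[, a]]
        gg <- gg + dNdy[a] * ux[el[, a]] + dNdx[a] * uy[el[, a]]
      }
      list(ex = exg, ey = eyg, gxy = gg)
    })
  } else {
    tg <- .tri_geom(mesh)
    inv2A <- 1 / (2 * tg$A)
    ex <- inv2A * (tg$b[, 1] * ux[el[, 1]] + tg$b[, 2] * ux[el[, 2]] +
                     tg$b[, 3] * ux[el[, 3]])
    ey <- inv2A * (tg$c[, 1] * uy[el[, 1]] + tg$c[, 2] * uy[el[, 2]] +
                     tg$c[, 3] * uy[el[, 3]])
    gxy <- inv2A * (tg$c[, 1] * ux[el[, 1]] + tg$c[, 2] * ux[el[, 2]] +
                      tg$c[, 3] * ux[el[, 3]] +
                      tg$b[, 1] * uy[el[, 1]] + tg$b[, 2] * uy[el[, 2]] +
                      tg$b[, 3] * uy[el[, 3]])
  }
  lam <- mat$E * mat$nu / ((1 + mat$nu) * (1 - 2 * mat$nu))
  mu <- mat$E / (2 * (1 + mat$nu))
  energy <- function(exs, eys, gs) {
    emx <- exs - e0[, 1]; emy <- eys - e0[, 2]
    emz <- -e0[, 3]                    # plane strain: total eps_zz = 0
    gm <- gs - e0[, 4]
    tr <- emx + emy + emz
    sxg <- lam * tr + 2 * mu * emx
    syg <- lam * tr + 2 * mu * emy
    szg <- lam * tr + 2 * mu * emz
    tg <- mu * gm
    if (sed_strain == "mechanical") {
      0.5 * (sxg * emx + syg * emy + szg * emz + tg * gm)
    } else {
      0.5 * (sxg * exs + syg * eys + tg * gs)
    }
  }
  emx <- ex - e0[, 1]; emy <- ey - e0[, 2]
  emz <- -e0[, 3]
  gm <- gxy - e0[, 4]
  tr <- emx + emy + emz
  sx <- lam * tr + 2 * mu * emx
  sy <- lam * tr + 2 * mu * emy
  sz <- lam * tr + 2 * mu * emz
  txy <- mu * gm
  sed <- if (is.null(gp_strains)) {
    energy(ex, ey, gxy)                # constant-strain triangles
  } else {
    Reduce(`+`, lapply(gp_strains, function(g)
      energy(g$ex, g$ey, g$gxy))) / 4
  }
  structure(list(u = cbind(x = ux, y = uy),
                 stress = cbind(sx = sx, sy = sy, sz = sz, txy = txy),
                 strain = cbind(ex = ex, ey = ey, gxy = gxy),
                 strain_mech = cbind(ex = emx, ey = emy, ez = emz, gxy = gm),
                 sed = unname(sed)), class = "fe_solution")
}

#' Per-element strain energy density
#'
#' `U = sigma_ij eps_ij / 2` with the mechanical (eigenstrain-subtracted)
#' strain conjugate to the stress; units J/cm^3 in the mm-MPa system.
#'
#' @param solution An `fe_solution`.
#' @return Numeric vector of non-negative energy densities.
#' @export
element_sed <- function(solution) {
  stopifnot(inherits(solution, "fe_solution"))
  if (!is.null(solution$sed)) return(unname(solution$sed))
  s <- solution$stress; e <- solution$strain_mech
  unname(0.5 * (s[, 1] * e[, 1] + s[, 2] * e[, 2] + s[, 3] * e[, 3] +
                  s[, 4] * e[, 4]))
}
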