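# Post-ingrowth mechanical characterization: apparent compressive stiffness
# of the porous anchor, and a push-out fixation model combining Coulomb
# friction on the anchor-bone contact with Johnson-Cook elasto-plastic
# shearing (and erosion) of the newly formed bone bridges in the pore
# throats.

#' Apparent compressive stiffness
#'
#' Displacement-controlled compression: `u_y = -strain * y` is prescribed on
#' the nodes of a boundary set (the outer surface for anchor meshes, the top
#' face for rectangular benchmarks) with the quarter-slice symmetry planes
#' active, and the apparent slope of the stress-strain curve is the
#' volume-averaged axial stress divided by the applied strain.
#'
#' @param mesh A 2D `fe_mesh`.
#' @param mat A `material_state` (pre- or post-ingrowth densities mapped to
#'   moduli).
#' @param strain_level Applied compressive strain (default 1e-3; the
#'   response is linear, so the slope is strain-independent).
#' @param boundary_set Boundary face set to drive (default `"interface"`;
#'   use `"ymax"` for [rect_mesh()]).
#' @return Apparent modulus, MPa.
#' @export
compression_stiffness <- function(mesh, mat, strain_level = 1e-3,
                                  boundary_set = "interface") {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(mat, "material_state"))
  bf <- mesh$boundary$faces
  dn <- sort(unique(c(bf$n1[bf$set == boundary_set],
                      bf$n2[bf$set == boundary_set])))
  if (length(dn) == 0) stop("no boundary faces in set '", boundary_set, "'")
  bcs <- rbind(bc_symmetry(mesh),
               bc_fix(dn, 2L, -strain_level * mesh$nodes[dn, 2]))
  sol <- assemble_and_solve(mesh, mat, load_case(bcs = bcs))
  mean_sy <- sum(sol$stress[, "sy"] * mesh$volume) / sum(mesh$volume)
  -mean_sy / strain_level
}

#' Johnson-Cook flow stress
#'
#' Quasi-static isothermal hardening law `sigma_y = A + B_h eps^n` (GPa).
#'
#' @param plastic_strain Equivalent plastic strain (>= 0).
#' @param params A [jc_params()].
#' @return Yield stress, GPa.
#' @examples
#' jc_yield_stress(c(0, 0.1, 1), jc_params())
#' @export
jc_yield_stress <- function(plastic_strain, params) {
  stopifnot(inherits(params, "jc_params"), all(plastic_strain >= 0))
  params$A + params$B_h * plastic_strain^params$n
}

#' Push-out simulation
#'
#' Displacement-controlled axial extraction of the anchor from its bone
#' layer. Resistance has two sources: (a) Coulomb friction on the
#' anchor-material contact faces of the interface, under the held swelling
#' pressure, regularized by an elastic slip tolerance (stick-slip); and
#' (b) post-ingrowth, the shearing of newly formed bone bridges - void
#' elements at the interface whose density has reached the bonding
#' threshold, merged with the surrounding bone. Bridges follow the
#' Johnson-Cook law in shear (von Mises, `tau = sigma_y / sqrt(3)`) and are
#' eroded (deleted from the load-bearing system) when their equivalent
#' plastic strain exceeds the erosion threshold. Forces are reported in N
#' for the quarter-slice of thickness `mesh$thickness`.
#'
#' @param mesh An anchor-only 2D `fe_mesh` with interface faces.
#' @param mat A `material_state`; post-ingrowth densities determine which
#'   interface void elements are bonded.
#' @param interface_pressure Held normal pressure, MPa (the swelling
#'   `|mean sigma_rr|`).
#' @param friction_mu Coulomb friction coefficient (default 0.4).
#' @param jc A [jc_params()].
#' @param max_displacement Push-out displacement, mm (default 0.5).
#' @param mode `"auto"` (post if any bonded bridge exists), `"pre"`
#'   (friction only) or `"post"`.
#' @param bond_threshold Density (g/cm^3) above which an interface void
#'   element counts as bonded bone (default 0.4).
#' @param n_steps Displacement increments.
#' @param slip_tol Elastic slip regularization length, mm.
#' @param shear_length Shear-zone length of a bridge, mm (default one
#'   element).
#' @return An object of class `pushout_result`: `curve` (displacement mm,
#'   force N), `peak_force` (N), `eroded_elements`, and the contact/bridge
#'   areas (mm^2).
#' @export
pushout <- function(mesh, mat, interface_pressure, friction_mu = 0.4,
                    jc = jc_params(), max_displacement = 0.5,
                    mode = c("auto", "pre", "post"), bond_threshold = 0.4,
                    n_steps = 200L, slip_tol = 0.01,
                    shear_length = mesh$h) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(mat, "material_state"),
            interface_pressure >= 0, friction_mu >= 0)
  mode <- match.arg(mode)
  faces <- mesh$interface$faces
  if (nrow(faces) == 0) stop("mesh has no interface faces")
  contact <- faces[mesh$region[faces$elem] == "ANCHOR", , drop = FALSE]
  a_contact <- sum(contact$w)

  bridge <- faces[mesh$region[faces$elem] == "VOID" &
                    mat$rho[faces$elem] >= bond_threshold, , drop = FALSE]
  if (mode == "pre") bridge <- bridge[0, , drop = FALSE]
  nb <- nrow(bridge)
  a_bridge <- sum(bridge$w)
  G_b <- if (nb > 0) {
    mat$E[bridge$elem] / (2 * (1 + mat$nu[bridge$elem]))
  } else numeric(0)

  tau_y <- function(ep) 1000 * jc_yield_stress(ep, jc) / sqrt(3)  # MPa
  f_peak_fric <- friction_mu * interface_pressure * a_contact

  disp <- seq(0, max_displacement, length.out = n_steps + 1)
  force <- numeric(length(disp))
  ep <- numeric(nb)                 # equivalent plastic strain per bridge
  eroded <- logical(nb)
  for (s in seq_along(disp)) {
    d <- disp[s]
    f_fric <- min(d / slip_tol, 1) * f_peak_fric
    f_br <- 0
    if (nb > 0) {
      gam <- d / shear_length
      live <- !eroded
      if (any(live)) {
        tau_tr <- G_b[live] * (gam - sqrt(3) * ep[live])
        yld <- tau_tr > tau_y(ep[live])
        if (any(yld)) {
          idx <- which(live)[yld]
          # monotone loading: solve G (gam - sqrt(3) ep) = tau_y(ep)
          lo <- ep[idx]
          hi <- rep(gam / sqrt(3), length(idx))
          for (it in 1:60) {
            mid <- (lo + hi) / 2
            fmid <- G_b[idx] * (gam - sqrt(3) * mid) - tau_y(mid)
            lo[fmid > 0] <- mid[fmid > 0]
            hi[fmid <= 0] <- mid[fmid <= 0]
          }
          ep[idx] <- (lo + hi) / 2
        }
        new_eroded <- live & (ep >= jc$erosion_strain)
        eroded <- eroded | new_eroded
        live <- !eroded
        if (any(live)) {
          tau <- pmin(G_b[live] * (gam - sqrt(3) * ep[live]),
                      tau_y(ep[live]))
          tau <- pmax(tau, 0)
          f_br <- sum(tau * bridge$w[live])
        }
      }
    }
    force[s] <- f_fric + f_br
  }
  structure(list(curve = data.frame(displacement = disp, force = force),
                 peak_force = max(force),
                 eroded_elements = if (nb > 0) bridge$elem[eroded]
                                   else integer(0),
                 contact_area = a_contact, bridge_area = a_bridge,
                 friction_peak = f_peak_fric, mode = mode),
            class = "pushout_result")
}

#' @export
print.pushout_result <- function(x, ...) {
  cat(sprintf(paste0("<pushout_result> peak force %.1f N (friction bound ",
                     "%.1f N, bridge area %.2f mm^2, %d eroded)\n"),
              x$peak_force, x$friction_peak, x$bridge_area,
              length(x$eroded_elements)))
  invisible(x)
}
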