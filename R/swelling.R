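# Hygro-elastic swelling of the constrained anchor. The anchor absorbs
# moisture and expands; confined by the surrounding bone, the expansion turns
# into compressive radial stress at the bone-anchor interface (and tensile
# hoop stress in the bone). The area-averaged radial interface stress is the
# load handed to the ingrowth stage.

#' Hygroscopic swelling eigenstrain
#'
#' Linear sorption model: the stress-free swelling strain is
#' `beta_h * (moisture - moisture_ref)` on the diagonal, zero shear.
#'
#' @param params A [swelling_params()].
#' @return Length-3 numeric vector of principal swelling strains.
#' @examples
#' hygroscopic_strain(swelling_params())  # 0.9920 * 0.08672 = 0.0860262
#' @export
hygroscopic_strain <- function(params) {
  stopifnot(inherits(params, "swelling_params"))
  d_alpha <- params$moisture - params$moisture_ref
  beta <- params$beta_h
  if (length(beta) == 1) beta <- rep(beta, 3)
  beta * d_alpha
}

#' Constrained swelling of the anchor in its bone layer
#'
#' Applies the hygroscopic eigenstrain to the ANCHOR elements of a
#' quarter-slice mesh that includes the bone layer, with symmetry boundary
#' conditions, and solves the hygro-elastic problem. By default the outer
#' bone surface is traction-free (a finite bone collar, which reproduces the
#' tensile hoop stress the expanding anchor induces in the bone);
#' `fix_outer = TRUE` models rigid far-field confinement instead. The wet modulus is used for the
#' swollen anchor. Moisture is imposed at its equilibrium value (no
#' diffusion transient).
#'
#' @param mesh An `fe_mesh` built with `include_bone = TRUE`.
#' @param mat Optional `material_state`; by default built from `params`
#'   (wet anchor modulus) and the standard dummy/bone properties.
#' @param params A [swelling_params()].
#' @param fix_outer Fix the outer bone surface (default FALSE).
#' @return An `fe_solution`.
#' @export
simulate_constrained_swelling <- function(mesh, mat = NULL, params,
                                          fix_outer = FALSE) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(params, "swelling_params"))
  if (is.null(mat)) {
    mat <- material_state(mesh, anchor_E = params$E_wet,
                          anchor_nu = params$nu)
  }
  eps <- hygroscopic_strain(params)
  e0 <- matrix(0, nrow(mesh$elems), 4)
  anchor <- mesh$region == "ANCHOR"
  e0[anchor, 1] <- eps[1]
  e0[anchor, 2] <- eps[2]
  e0[anchor, 3] <- eps[3]
  bcs <- bc_symmetry(mesh)
  if (fix_outer && length(mesh$boundary$outer_nodes) > 0) {
    bcs <- rbind(bcs,
                 bc_fix(mesh$boundary$outer_nodes, 1L),
                 bc_fix(mesh$boundary$outer_nodes, 2L))
  }
  assemble_and_solve(mesh, mat, load_case(eigenstrain = e0, bcs = bcs))
}

#' Average radial stress at the bone-anchor interface
#'
#' Area-weighted mean of the radial stress component `sigma_rr = r' S r`
#' over the interface faces, evaluated from the anchor-side element stress.
#' Face weights are projected onto the nominal cylindrical interface so the
#' staircase discretization integrates to the true interface area.
#'
#' @param solution An `fe_solution`.
#' @param mesh The `fe_mesh` the solution was computed on.
#' @param faces Interface face table (default `mesh$interface$faces`).
#' @return An object of class `interface_stress`: `mean_radial_stress`
#'   (MPa, negative = compressive), `interface_area` (mm^2) and the
#'   per-face `samples`.
#' @export
average_radial_stress <- function(solution, mesh,
                                  faces = mesh$interface$faces) {
  stopifnot(inherits(solution, "fe_solution"))
  if (is.null(faces) || nrow(faces) == 0)
    stop("empty interface face set")
  s <- solution$stress[faces$elem, , drop = FALSE]
  r <- sqrt(faces$cx^2 + faces$cy^2)
  rx <- faces$cx / r; ry <- faces$cy / r
  srr <- s[, "sx"] * rx^2 + s[, "sy"] * ry^2 + 2 * s[, "txy"] * rx * ry
  w <- faces$w
  structure(list(mean_radial_stress = sum(srr * w) / sum(w),
                 interface_area = sum(w),
                 samples = data.frame(elem = faces$elem, sigma_rr = srr,
                                      weight = w)),
            class = "interface_stress")
}

#' @export
print.interface_stress <- function(x, ...) {
  cat(sprintf(paste0("<interface_stress> mean sigma_rr = %.3f MPa over ",
                     "%.2f mm^2 (%d faces)\n"),
              x$mean_radial_stress, x$interface_area, nrow(x$samples)))
  invisible(x)
}
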