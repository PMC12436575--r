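# The core algorithm: iterative strain-energy-density remodeling of the void
# region with osteoconnectivity gating. Each iteration solves the FE problem
# under the swelling-derived interface pressure, computes the stimulus
# S = U/rho for every element, lets only gate-eligible void elements update
# their apparent density by a forward Euler step of the remodeling rule, and
# maps density to stiffness. Eligibility spreads through the element
# adjacency graph from the bone-anchor interface inward, one neighbor layer
# at a time, which is what makes bone formation sequential.

#' Remodeling stimulus field
#'
#' `S = U / rho` per element (J/g): strain energy density per unit apparent
#' density, the mechanosignal of strain-energy-density remodeling.
#' Densities below `rho_min` are clamped before dividing.
#'
#' @param solution An `fe_solution`.
#' @param mat A `material_state` (supplies `rho`, g/cm^3).
#' @param rho_min Density floor used in the division.
#' @return Numeric vector of stimuli, J/g.
#' @export
compute_stimulus <- function(solution, mat, rho_min = 0.01) {
  U <- element_sed(solution)
  U / pmax(mat$rho, rho_min)
}

#' Forward Euler remodeling update
#'
#' One time step of the lazy-zone remodeling rule: apposition at rate
#' `B (S - (1+delta) k)` above the lazy zone, no change inside it,
#' resorption at rate `B (S - (1-delta) k)` below it; the result is clamped
#' to `[rho_min, rho_max]`. Vectorized over elements.
#'
#' @param rho_prev Densities at the previous step, g/cm^3.
#' @param S_prev Stimuli at the previous step, J/g.
#' @param params A [remodeling_params()].
#' @return Updated densities, g/cm^3.
#' @examples
#' p <- remodeling_params()
#' euler_update(0.01, 0.0050, p)   # 0.01 + 0.01 * (0.0050 - 0.0044)
#' @export
euler_update <- function(rho_prev, S_prev, params) {
  hi <- (1 + params$delta) * params$k
  lo <- (1 - params$delta) * params$k
  drho <- numeric(length(rho_prev))
  up <- S_prev > hi
  dn <- S_prev < lo
  drho[up] <- params$B * params$dt * (S_prev[up] - hi)
  drho[dn] <- params$B * params$dt * (S_prev[dn] - lo)
  pmin(pmax(rho_prev + drho, params$rho_min), params$rho_max)
}

#' Osteoconnectivity gate: which void elements may densify
#'
#' In the first iteration only void elements on the bone-anchor interface
#' (open pore throats) are eligible. From the second iteration on, a void
#' element joins the eligible set once any neighbor's current density
#' exceeds `alpha_gate` times that neighbor's initial density; eligibility
#' is permanent once acquired. The gate factor controls the ingrowth rate:
#' `alpha_gate = 1` lets bone advance one neighbor layer per iteration,
#' stricter gates (1.25, 1.5) hold the front until the previous layer has
#' densified by 25% or 50%.
#'
#' @param iteration Iteration number (1-based).
#' @param adjacency Neighbor lists (see [build_adjacency()]).
#' @param density Current densities, g/cm^3.
#' @param initial_density Densities recorded at iteration 0.
#' @param interface_elements Element ids on the bone-anchor interface.
#' @param void_elements Logical mask (or ids) of VOID elements.
#' @param params A [remodeling_params()] (supplies `alpha_gate`).
#' @param eligible Logical eligibility vector from the previous iteration
#'   (ignored at iteration 1).
#' @return Logical eligibility vector over elements.
#' @export
gate_eligibility <- function(iteration, adjacency, density, initial_density,
                             interface_elements, void_elements, params,
                             eligible = NULL) {
  nel <- length(density)
  void <- logical(nel)
  void[void_elements] <- TRUE
  if (iteration <= 1) {
    el <- logical(nel)
    el[intersect(which(void), interface_elements)] <- TRUE
    return(el)
  }
  stopifnot(!is.null(eligible))
  grown <- which(density > params$alpha_gate * initial_density)
  if (length(grown) > 0) {
    nb <- unique(unlist(adjacency[grown], use.names = FALSE))
    newly <- logical(nel)
    newly[nb] <- TRUE
    eligible <- eligible | (newly & void)
  }
  eligible
}

#' Density-to-modulus law for newly formed bone
#'
#' Power law `E(rho) = E_ref (rho / rho_ref)^gamma` through the two anchor
#' points of the model's material set: the dummy void material
#' (0.01 g/cm^3, 0.05 MPa) and trabecular bone (0.8 g/cm^3, 1940.48 MPa).
#' The implied exponent `gamma = log(E_ref/E_min)/log(rho_ref/rho_min)
#' ~ 2.41` sits in the classical square-to-cube range of density-modulus
#' relations for trabecular bone. Floored at `E_min`.
#'
#' @param rho Apparent density, g/cm^3.
#' @param E_ref,rho_ref Bone anchor point (MPa, g/cm^3).
#' @param E_min,rho_min Dummy-material anchor point.
#' @return Elastic modulus, MPa.
#' @examples
#' density_to_modulus(c(0.01, 0.4, 0.8))
#' @export
density_to_modulus <- function(rho, E_ref = 1940.48, rho_ref = 0.8,
                               E_min = 0.05, rho_min = 0.01) {
  gamma <- log(E_ref / E_min) / log(rho_ref / rho_min)
  pmax(E_min, E_ref * (rho / rho_ref)^gamma)
}

#' Run the osteoconnectivity-gated bone ingrowth loop
#'
#' Iterates: FE solve under the interface pressure -> strain energy density
#' -> stimulus -> osteoconnectivity gate -> Euler density update of eligible
#' void elements -> density-to-modulus mapping -> metrics. Stops at
#' homeostasis (no element's density changes by more than
#' `params$convergence_tol` relatively) or after `params$max_iterations`.
#'
#' The pressure is applied on the anchor-material faces of the interface;
#' open pore throats carry no contact pressure (bone, not the anchor
#' surface, occupies them), which is what shields the soft void elements
#' from the full interface load and gives the gradual densification the
#' gate acts on.
#'
#' @param mesh An anchor-only `fe_mesh` (`include_bone = FALSE`).
#' @param mat A `material_state`; void elements should start at the density
#'   lower bound with the dummy modulus.
#' @param load_pressure Interface pressure magnitude, MPa (positive =
#'   compressive), typically `|mean sigma_rr|` from the swelling stage.
#' @param params A [remodeling_params()].
#' @param modulus_law Function mapping density to modulus (MPa), default
#'   [density_to_modulus()].
#' @param ramp_iterations If > 0, the load saturates as
#'   `1 - exp(-3 i / ramp_iterations)`; 0 (default) applies it fully from
#'   iteration 1.
#' @param load_faces `"anchor"` (default) or `"all"`: which interface faces
#'   carry the pressure.
#' @param iterations Optional cap overriding `params$max_iterations`.
#' @param record_densities Keep a density snapshot per iteration.
#' @param verbose Print one line per iteration.
#' @return An object of class `ingrowth_history`: `metrics` (one row per
#'   iteration: grown_element_count, ingrowth_depth_mm,
#'   filled_volume_ratio, added_mass_g, eligible_count, max_rel_change),
#'   final `rho`, `rho_init`, `eligible`, and `densities` if recorded.
#' @export
run_ingrowth <- function(mesh, mat, load_pressure, params,
                         modulus_law = density_to_modulus,
                         ramp_iterations = 0L,
                         load_faces = c("anchor", "all"),
                         iterations = NULL,
                         record_densities = FALSE, verbose = FALSE) {
  stopifnot(inherits(mesh, "fe_mesh"), inherits(mat, "material_state"),
            inherits(params, "remodeling_params"))
  load_faces <- match.arg(load_faces)
  n_iter <- if (is.null(iterations)) params$max_iterations
            else as.integer(iterations)
  nel <- nrow(mesh$elems)
  void <- mesh$region == "VOID"
  rho <- mat$rho
  rho_init <- rho
  E <- mat$E
  nu <- mat$nu

  faces <- mesh$interface$faces
  if (nrow(faces) == 0) stop("mesh has no interface faces")
  if (load_faces == "anchor")
    faces <- faces[mesh$region[faces$elem] == "ANCHOR", , drop = FALSE]
  bcs <- bc_symmetry(mesh)
  v_void <- mesh$volume[void]
  vol_void <- sum(v_void)
  r_c <- sqrt(mesh$centroid[, 1]^2 + mesh$centroid[, 2]^2)

  eligible <- logical(nel)
  densities <- if (record_densities) vector("list", n_iter) else NULL
  rows <- vector("list", n_iter)
  n_done <- 0L
  for (i in seq_len(n_iter)) {
    amp <- if (ramp_iterations > 0) 1 - exp(-3 * i / ramp_iterations) else 1
    mat_i <- structure(list(E = E, nu = nu, rho = rho),
                       class = "material_state")
    sol <- assemble_and_solve(
      mesh, mat_i,
      load_case(pressure = list(faces = faces, p = amp * load_pressure),
                bcs = bcs))
    S <- compute_stimulus(sol, mat_i, rho_min = params$rho_min)
    eligible <- gate_eligibility(i, mesh$adjacency, rho, rho_init,
                                 mesh$interface$elements, which(void),
                                 params, eligible)
    upd <- eligible & void
    rho_new <- rho
    rho_new[upd] <- euler_update(rho[upd], S[upd], params)
    max_rel <- if (any(void)) max(abs(rho_new[void] - rho[void]) /
                                    rho[void]) else 0
    rho <- rho_new
    E[void] <- modulus_law(rho[void])

    grown <- void & (rho > rho_init + 1e-12)
    depth <- if (any(grown)) max(mesh$anchor_radius - r_c[grown]) else 0
    filled <- void & (rho >= params$fill_threshold)
    rows[[i]] <- data.frame(
      iteration = i,
      grown_element_count = sum(grown),
      ingrowth_depth_mm = depth,
      filled_volume_ratio = if (vol_void > 0)
        sum(mesh$volume[filled]) / vol_void else 0,
      added_mass_g = sum((rho[void] - rho_init[void]) * v_void) * 1e-3,
      eligible_count = sum(upd),
      max_rel_change = max_rel,
      load_amplitude = amp)
    if (record_densities) densities[[i]] <- rho
    n_done <- i
    if (verbose)
      message(sprintf(paste0("iter %3d: grown %6d, depth %.3f mm, fill ",
                             "%.3f, d_rho_max %.4f"),
                      i, sum(grown), depth,
                      rows[[i]]$filled_volume_ratio, max_rel))
    if (max_rel < params$convergence_tol) break
  }
  structure(list(metrics = do.call(rbind, rows[seq_len(n_done)]),
                 rho = rho, rho_init = rho_init, eligible = eligible,
                 densities = if (record_densities)
                   densities[seq_len(n_done)] else NULL,
                 params = params, load_pressure = load_pressure,
                 converged = n_done < n_iter ||
                   rows[[n_done]]$max_rel_change < params$convergence_tol),
            class = "ingrowth_history")
}

#' @export
print.ingrowth_history <- function(x, ...) {
  m <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(paste0("<ingrowth_history> %d iterations, load %.2f MPa\n",
                     "  grown %d elements, depth %.3f mm, filled ratio ",
                     "%.3f, added mass %.4g g\n"),
              nrow(x$metrics), x$load_pressure, m$grown_element_count,
              m$ingrowth_depth_mm, m$filled_volume_ratio, m$added_mass_g))
  invisible(x)
}

#' Summary metrics of an ingrowth run
#'
#' Grown-element count (density above initial), maximum ingrowth depth
#' (radial distance inward from the interface surface), added bone mass
#' `sum (rho - rho_init) V` in grams, and filled volume ratio (volume
#' fraction of the void region at or above the fill threshold).
#'
#' @param history An `ingrowth_history`.
#' @param mesh The mesh the run used.
#' @param fill_threshold Density threshold for "filled" (default from the
#'   run's parameters).
#' @return A list with `depth_mm`, `filled_volume_ratio`, `added_mass_g`,
#'   `grown_count`.
#' @export
ingrowth_metrics <- function(history, mesh,
                             fill_threshold = history$params$fill_threshold) {
  stopifnot(inherits(history, "ingrowth_history"))
  void <- mesh$region == "VOID"
  rho <- history$rho; rho0 <- history$rho_init
  grown <- void & (rho > rho0 + 1e-12)
  r_c <- sqrt(mesh$centroid[, 1]^2 + mesh$centroid[, 2]^2)
  vol_void <- sum(mesh$volume[void])
  list(depth_mm = if (any(grown))
         max(mesh$anchor_radius - r_c[grown]) else 0,
       filled_volume_ratio = if (vol_void > 0)
         sum(mesh$volume[void & rho >= fill_threshold]) / vol_void else 0,
       added_mass_g = sum((rho[void] - rho0[void]) * mesh$volume[void]) *
         1e-3,
       grown_count = sum(grown))
}
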