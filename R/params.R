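#' Pore-size specification for the synthetic porosity generator
#'
#' Describes the salt-leached pore population of a porous anchor: pore
#' diameters are drawn uniformly from `mean_diameter +/- half_band` and pores
#' (disks in 2D, spheres in 3D) are inserted at random positions inside the
#' anchor until a target porosity is reached. Overlap between pores is
#' permitted; interconnectivity of the resulting void space is emergent, as in
#' the NaCl-crystal leaching process the generator emulates.
#'
#' @param mean_diameter Mean pore diameter in micrometres. The study bands are
#'   300, 450 and 600 um.
#' @param half_band Half-width of the uniform diameter band in micrometres
#'   (default 100 um).
#' @param target_porosity Void volume fraction to reach inside the anchor
#'   (default 0.6).
#' @param rng_seed Integer seed; fixing it makes the realization bit-identical.
#'
#' @return An object of class `pore_spec`.
#' @examples
#' pore_spec(450, 100, 0.6, rng_seed = 7)
#' @export
pore_spec <- function(mean_diameter, half_band = 100, target_porosity = 0.6,
                      rng_seed = 1L) {
  stopifnot(is.numeric(mean_diameter), length(mean_diameter) == 1,
            mean_diameter > 0)
  stopifnot(half_band >= 0, mean_diameter - half_band > 0)
  stopifnot(target_porosity >= 0, target_porosity < 1)
  structure(list(mean_diameter = mean_diameter, half_band = half_band,
                 target_porosity = target_porosity,
                 rng_seed = as.integer(rng_seed)),
            class = "pore_spec")
}

#' @export
print.pore_spec <- function(x, ...) {
  cat(sprintf("<pore_spec> %g +/- %g um, target porosity %.2f, seed %d\n",
              x$mean_diameter, x$half_band, x$target_porosity, x$rng_seed))
  invisible(x)
}

#' Hygro-elastic swelling parameters
#'
#' Parameters of the linear hygroscopic swelling model: the free swelling
#' eigenstrain is `beta_h * (moisture - moisture_ref)` on the diagonal of the
#' strain tensor. Defaults are the measured values for the 85/15 MMA/AA
#' co-polymer swelled in bovine serum.
#'
#' @param beta_h Hygroscopic swelling coefficient, m^3/kg. Either a scalar
#'   (isotropic) or a length-3 vector of principal coefficients.
#' @param moisture Equilibrium moisture concentration, kg/m^3.
#' @param moisture_ref Reference (initial) moisture concentration, kg/m^3.
#' @param E_dry,E_wet Elastic modulus of the anchor co-polymer in dry and wet
#'   conditions, MPa.
#' @param nu Poisson ratio of the anchor co-polymer.
#' @param ramp_iterations Number of remodeling iterations over which the
#'   swelling-derived load saturates exponentially when re-applied in the
#'   ingrowth model; 0 applies the full load from the first iteration
#'   (swelling equilibrates quickly compared to remodeling timescales).
#'
#' @return An object of class `swelling_params`.
#' @export
swelling_params <- function(beta_h = 0.9920, moisture = 0.08672,
                            moisture_ref = 0, E_dry = 479, E_wet = 433,
                            nu = 0.25, ramp_iterations = 0L) {
  stopifnot(all(beta_h >= 0), length(beta_h) %in% c(1L, 3L))
  stopifnot(moisture >= moisture_ref, moisture_ref >= 0)
  stopifnot(E_dry > 0, E_wet > 0, nu > -1, nu < 0.5)
  structure(list(beta_h = beta_h, moisture = moisture,
                 moisture_ref = moisture_ref, E_dry = E_dry, E_wet = E_wet,
                 nu = nu, ramp_iterations = as.integer(ramp_iterations)),
            class = "swelling_params")
}

#' Bone remodeling / ingrowth parameters
#'
#' Parameters of the strain-energy-density remodeling rule with a lazy zone,
#' its forward-Euler integration, and the osteoconnectivity gate. Units follow
#' the mm-MPa-g/cm^3 system: strain energy density in J/cm^3 (numerically
#' MPa), apparent density in g/cm^3, so the stimulus S = U/rho is in J/g.
#'
#' @param B Remodeling rate constant, (g/cm^3)^2 (MPa * time unit)^-1.
#' @param k Reference (homeostatic) stimulus, J/g.
#' @param delta Lazy-zone half-width as a fraction of `k`; no density change
#'   occurs while `(1-delta)k < S < (1+delta)k`.
#' @param dt Time increment of the forward Euler step.
#' @param rho_min,rho_max Lower/upper bounds on apparent density, g/cm^3.
#' @param alpha_gate Osteoconnectivity gate factor (>= 1): a void element
#'   becomes eligible for densification once some neighbor's density exceeds
#'   `alpha_gate` times that neighbor's initial density. 1 is the relaxed
#'   gate, 1.25 moderate, 1.5 strict.
#' @param convergence_tol Homeostasis threshold: the loop stops when no
#'   element's density changes by more than this fraction in an iteration.
#' @param max_iterations Iteration cap.
#' @param fill_threshold Density (g/cm^3) above which a void element counts as
#'   "filled" in the filled-volume-ratio metric (default half bone density).
#'
#' @return An object of class `remodeling_params`.
#' @export
remodeling_params <- function(B = 1.0, k = 0.004, delta = 0.10, dt = 0.01,
                              rho_min = 0.01, rho_max = 1.7,
                              alpha_gate = 1.0, convergence_tol = 0.02,
                              max_iterations = 100L, fill_threshold = 0.4) {
  stopifnot(B > 0, k > 0, delta >= 0, delta < 1, dt > 0)
  stopifnot(rho_min > 0, rho_min < rho_max, alpha_gate >= 1)
  stopifnot(convergence_tol > 0, max_iterations >= 1)
  structure(list(B = B, k = k, delta = delta, dt = dt, rho_min = rho_min,
                 rho_max = rho_max, alpha_gate = alpha_gate,
                 convergence_tol = convergence_tol,
                 max_iterations = as.integer(max_iterations),
                 fill_threshold = fill_threshold),
            class = "remodeling_params")
}

#' Johnson-Cook plasticity parameters for newly formed bone
#'
#' Quasi-static, isothermal Johnson-Cook hardening law
#' `sigma_y = A + B_h * eps^n` (GPa) with an equivalent-plastic-strain erosion
#' criterion: elements whose plastic strain exceeds `erosion_strain` are
#' deleted from the load-bearing system.
#'
#' @param A Initial yield strength, GPa.
#' @param B_h Hardening modulus, GPa.
#' @param n Hardening exponent.
#' @param erosion_strain Equivalent plastic strain at which an element erodes.
#'
#' @return An object of class `jc_params`.
#' @export
jc_params <- function(A = 0.05, B_h = 0.1, n = 0.08, erosion_strain = 0.3) {
  stopifnot(A > 0, B_h >= 0, n > 0, n <= 1, erosion_strain > 0)
  structure(list(A = A, B_h = B_h, n = n, erosion_strain = erosion_strain),
            class = "jc_params")
}
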