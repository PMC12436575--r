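# Orchestration and reproducibility layer: a serializable run configuration
# and the end-to-end campaign generate -> swell -> ingrow -> compress ->
# push-out, per pore-size band.

#' Campaign configuration
#'
#' All parameters of an end-to-end run, serializable to YAML and
#' round-tripping losslessly. Defaults are the standard model parameter set
#' (wet-anchor modulus 433 MPa, bone 1940.48 MPa, remodeling B = 1,
#' k = 0.004 J/g, delta = 10%, dt = 0.01, density bounds 0.01/1.7 g/cm^3,
#' friction 0.4, JC 0.05/0.1/0.08 GPa).
#'
#' @param pore_means Mean pore diameters to study, um.
#' @param pore_band Half-band of the pore diameter distribution, um.
#' @param porosity Target porosity.
#' @param seed Base RNG seed; band `b` uses `seed + b - 1`.
#' @param element_size FE grid seed size, mm.
#' @param dim 2 or 3 (3 is geometry-only).
#' @param anchor_radius,slice_thickness,bone_layer Geometry, mm.
#' @param alpha_gate Osteoconnectivity gate factor.
#' @param iterations Ingrowth iterations per run.
#' @param swelling A [swelling_params()].
#' @param remodeling A [remodeling_params()].
#' @param jc A [jc_params()].
#' @param friction_mu Interface friction coefficient.
#' @param out_dir Output directory (`NULL`: no files written).
#' @return An object of class `run_config`.
#' @export
run_config <- function(pore_means = c(300, 450, 600), pore_band = 100,
                       porosity = 0.6, seed = 1L, element_size = 0.05,
                       dim = 2, anchor_radius = 4, slice_thickness = 2,
                       bone_layer = 1, alpha_gate = 1, iterations = 40L,
                       swelling = swelling_params(),
                       remodeling = remodeling_params(alpha_gate = alpha_gate),
                       jc = jc_params(), friction_mu = 0.4,
                       out_dir = NULL) {
  cfg <- list(pore_means = pore_means, pore_band = pore_band,
              porosity = porosity, seed = as.integer(seed),
              element_size = element_size, dim = dim,
              anchor_radius = anchor_radius,
              slice_thickness = slice_thickness, bone_layer = bone_layer,
              alpha_gate = alpha_gate, iterations = as.integer(iterations),
              swelling = unclass(swelling), remodeling = unclass(remodeling),
              jc = unclass(jc), friction_mu = friction_mu,
              out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Read / write a campaign configuration
#'
#' @param file YAML path.
#' @param config A `run_config`.
#' @return `read_config` returns a `run_config`; `write_config` the path.
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  cfg <- run_config()
  for (nm in names(raw)) {
    if (nm %in% c("swelling", "remodeling", "jc")) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], raw[[nm]])
    } else cfg[[nm]] <- raw[[nm]]
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg$iterations <- as.integer(cfg$iterations)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

.cfg_swelling <- function(cfg) do.call(swelling_params, cfg$swelling)
.cfg_remodeling <- function(cfg) {
  p <- cfg$remodeling
  p$alpha_gate <- cfg$alpha_gate
  do.call(remodeling_params, p)
}
.cfg_jc <- function(cfg) do.call(jc_params, cfg$jc)

#' Run one pipeline stage chain for a single pore band
#'
#' generate -> mesh -> swell -> ingrow -> compress (pre/post) -> push-out
#' (pre/post). Used by [run_campaign()] and the acceptance tooling.
#'
#' @param cfg A `run_config`.
#' @param pore_mean Mean pore diameter, um.
#' @param seed RNG seed for this realization.
#' @param stages Character subset of `c("swell", "ingrow", "mechanics")`.
#' @return List with the domain, meshes, swelling result, ingrowth history
#'   and mechanics results (as requested).
#' @export
run_band <- function(cfg, pore_mean, seed,
                     stages = c("swell", "ingrow", "mechanics")) {
  spec <- pore_spec(pore_mean, cfg$pore_band, cfg$porosity, rng_seed = seed)
  dom <- generate_porous_domain(spec, anchor_radius = cfg$anchor_radius,
                                slice_thickness = cfg$slice_thickness,
                                bone_layer = cfg$bone_layer, dim = cfg$dim)
  out <- list(domain = dom, seed = seed, pore_mean = pore_mean)
  sw <- .cfg_swelling(cfg)
  if ("swell" %in% stages) {
    mesh_sw <- mesh_domain(dom, cfg$element_size, include_bone = TRUE)
    sol <- simulate_constrained_swelling(mesh_sw, params = sw)
    out$interface_stress <- average_radial_stress(sol, mesh_sw)
    out$swelling_solution <- sol
  }
  if (any(c("ingrow", "mechanics") %in% stages)) {
    mesh <- mesh_domain(dom, cfg$element_size, include_bone = FALSE)
    out$mesh <- mesh
    mat0 <- material_state(mesh, anchor_E = sw$E_wet, anchor_nu = sw$nu)
    p_load <- abs(out$interface_stress$mean_radial_stress)
    out$load_pressure <- p_load
    rp <- .cfg_remodeling(cfg)
    hist <- run_ingrowth(mesh, mat0, p_load, rp,
                         ramp_iterations = sw$ramp_iterations,
                         iterations = cfg$iterations)
    out$history <- hist
    if ("mechanics" %in% stages) {
      mat_post <- mat0
      void <- mesh$region == "VOID"
      mat_post$rho <- hist$rho
      mat_post$E[void] <- density_to_modulus(hist$rho[void])
      out$stiffness_pre <- compression_stiffness(mesh, mat0)
      out$stiffness_post <- compression_stiffness(mesh, mat_post)
      jc <- .cfg_jc(cfg)
      out$pushout_pre <- pushout(mesh, mat0, p_load,
                                 friction_mu = cfg$friction_mu, jc = jc,
                                 mode = "pre")
      out$pushout_post <- pushout(mesh, mat_post, p_load,
                                  friction_mu = cfg$friction_mu, jc = jc,
                                  mode = "post")
    }
  }
  out
}

#' Run the full campaign over all pore bands
#'
#' Executes generate -> swell -> ingrow -> compress -> push-out for every
#' pore band in the configuration and assembles a report. With
#' `config$out_dir` set, writes per-band metrics CSVs, a JSON summary, the
#' pore lists and VTK snapshots of the final density field.
#'
#' @param config A `run_config`.
#' @param dry_run Validate the configuration and return without computing
#'   or writing anything.
#' @return An object of class `campaign_report`: `summary` (one row per
#'   band), `metrics` (per-iteration tables, named by band) and `config`.
#' @export
run_campaign <- function(config, dry_run = FALSE) {
  stopifnot(inherits(config, "run_config"))
  .cfg_swelling(config); .cfg_remodeling(config); .cfg_jc(config)  # validate
  if (dry_run) {
    return(structure(list(summary = NULL, metrics = NULL, config = config,
                          dry_run = TRUE), class = "campaign_report"))
  }
  bands <- config$pore_means
  res <- vector("list", length(bands))
  for (b in seq_along(bands)) {
    res[[b]] <- run_band(config, bands[b], config$seed + b - 1L)
  }
  summary <- do.call(rbind, lapply(res, function(r) {
    fin <- r$history$metrics[nrow(r$history$metrics), ]
    data.frame(pore_mean_um = r$pore_mean, seed = r$seed,
               porosity = r$domain$achieved_porosity,
               sigma_rr_MPa = r$interface_stress$mean_radial_stress,
               load_MPa = r$load_pressure,
               iterations = nrow(r$history$metrics),
               grown_count = fin$grown_element_count,
               depth_mm = fin$ingrowth_depth_mm,
               filled_volume_ratio = fin$filled_volume_ratio,
               added_mass_g = fin$added_mass_g,
               stiffness_pre_MPa = r$stiffness_pre,
               stiffness_post_MPa = r$stiffness_post,
               pushout_pre_N = r$pushout_pre$peak_force,
               pushout_post_N = r$pushout_post$peak_force)
  }))
  metrics <- lapply(res, function(r) r$history$metrics)
  names(metrics) <- paste0("pore", bands)
  report <- structure(list(summary = summary, metrics = metrics,
                           config = config, dry_run = FALSE),
                      class = "campaign_report")
  if (!is.null(config$out_dir)) .write_campaign(report, res, config)
  report
}

.write_campaign <- function(report, res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  utils::write.csv(report$summary, file.path(od, "summary.csv"),
                   row.names = FALSE)
  for (b in seq_along(res)) {
    tag <- paste0("pore", res[[b]]$pore_mean)
    utils::write.csv(res[[b]]$history$metrics,
                     file.path(od, paste0(tag, "_metrics.csv")),
                     row.names = FALSE)
    write_pores(res[[b]]$domain, file.path(od, paste0(tag, "_pores.csv")))
    write_vtk(res[[b]]$mesh, file.path(od, paste0(tag, "_final.vtk")),
              cell_data = list(region = res[[b]]$mesh$region,
                               density = res[[b]]$history$rho))
  }
  jsonlite::write_json(
    list(config = unclass(config),
         summary = report$summary),
    file.path(od, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  write_config(config, file.path(od, "config.yaml"))
  invisible(od)
}

#' @export
print.campaign_report <- function(x, ...) {
  if (isTRUE(x$dry_run)) {
    cat("<campaign_report> dry run: configuration valid\n")
    return(invisible(x))
  }
  cat("<campaign_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
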