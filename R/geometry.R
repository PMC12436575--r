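#' Generate a synthetic porous anchor geometry
#'
#' Emulates NaCl-crystal-leached porosity: pores (disks in 2D, spheres in 3D)
#' with diameters drawn uniformly from the band in `spec` are inserted at
#' uniformly random positions inside the anchor cross-section until the target
#' porosity is reached. Pores may overlap freely; the leaching process offers
#' no control over interconnectivity, so connectivity of the void space (and
#' the existence of isolated "pore islands") is emergent. The geometry is a
#' quarter slice of a cylindrical anchor surrounded by a bone layer, with
#' symmetry planes at x = 0 and y = 0.
#'
#' Porosity is tracked on an internal raster of the anchor cross-section. A
#' candidate pore that would overshoot the target by more than 0.02 is
#' discarded and redrawn, so the achieved porosity always lands within
#' +0.02 of the target. The realization is a deterministic function of
#' `spec$rng_seed`.
#'
#' @param spec A [pore_spec()].
#' @param anchor_radius Anchor radius, mm (default 4).
#' @param slice_thickness Axial slice thickness, mm (default 2).
#' @param bone_layer Thickness of the surrounding bone layer, mm (default 1).
#' @param dim 2 for the plane-strain cross-section (default), 3 for a
#'   volumetric quarter slice with spherical pores.
#' @param raster Raster cell size, mm, used to measure porosity (default
#'   0.02 in 2D, 0.05 in 3D).
#' @param max_attempts Insertion attempts before giving up with an error.
#' @param pores Optional data frame with columns `x`, `y` (, `z`) in mm and
#'   `diameter` in um, bypassing random insertion (fixtures / custom
#'   geometries).
#'
#' @return An object of class `porous_domain` with the pore table
#'   (`$pores`: x, y, z in mm, diameter in um) and `$achieved_porosity`.
#' @examples
#' dom <- generate_porous_domain(pore_spec(450, 100, 0.6, rng_seed = 7))
#' dom$achieved_porosity
#' @export
generate_porous_domain <- function(spec, anchor_radius = 4,
                                   slice_thickness = 2, bone_layer = 1,
                                   dim = 2, raster = NULL,
                                   max_attempts = 50000L, pores = NULL) {
  stopifnot(inherits(spec, "pore_spec"), anchor_radius > 0,
            slice_thickness > 0, bone_layer >= 0, dim %in% c(2, 3))
  if (is.null(raster)) raster <- if (dim == 2) 0.02 else 0.05
  R <- anchor_radius

  # raster of the anchor quarter section used to measure covered area
  nx <- ceiling(R / raster)
  nz <- if (dim == 3) ceiling(slice_thickness / raster) else 1L
  ci <- rep(seq_len(nx), times = nx * nz)
  cj <- rep(rep(seq_len(nx), each = nx), times = nz)
  ck <- rep(seq_len(nz), each = nx * nx)
  cx <- (ci - 0.5) * raster
  cy <- (cj - 0.5) * raster
  cz <- if (dim == 3) (ck - 0.5) * raster else rep(0, length(cx))
  inside <- cx^2 + cy^2 <= R^2
  grid <- list(ci = ci[inside], cj = cj[inside], ck = ck[inside],
               cx = cx[inside], cy = cy[inside], cz = cz[inside],
               s = raster, nx = nx, nz = nz, dim = dim)
  grid$lookup <- integer(nx * nx * nz)
  grid$lookup[grid$ci + (grid$cj - 1L) * nx + (grid$ck - 1L) * nx * nx] <-
    seq_along(grid$cx)
  n_in <- length(grid$cx)
  covered <- logical(n_in)

  if (!is.null(pores)) {
    stopifnot(all(c("x", "y", "diameter") %in% names(pores)))
    if (is.null(pores$z)) pores$z <- 0
    for (i in seq_len(nrow(pores))) {
      covered[.cells_in_ball(grid, pores$x[i], pores$y[i], pores$z[i],
                             pores$diameter[i] / 2000)] <- TRUE
    }
    achieved <- mean(covered)
    return(structure(list(spec = spec, anchor_radius = anchor_radius,
                          slice_thickness = slice_thickness,
                          bone_layer = bone_layer, dim = dim,
                          pores = pores, achieved_porosity = achieved,
                          raster = raster),
                     class = "porous_domain"))
  }

  # local RNG stream; global state is restored on exit
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$rng_seed)

  px <- py <- pz <- dum <- numeric(0)
  target <- spec$target_porosity
  porosity <- 0
  attempts <- 0L
  while (porosity < target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(paste0("porosity target %.2f not reached after %d ",
                          "insertion attempts (achieved %.3f); pores may be ",
                          "too large for the domain"),
                   target, max_attempts, porosity))
    }
    d_um <- stats::runif(1, spec$mean_diameter - spec$half_band,
                         spec$mean_diameter + spec$half_band)
    repeat {                       # center uniform in the quarter disk
      x <- stats::runif(1, 0, R); y <- stats::runif(1, 0, R)
      if (x^2 + y^2 <= R^2) break
    }
    z <- if (dim == 3) stats::runif(1, 0, slice_thickness) else 0
    hit <- .cells_in_ball(grid, x, y, z, d_um / 2000)
    n_new <- sum(!covered[hit])
    new_por <- porosity + n_new / n_in
    if (new_por > target + 0.02) next    # would overshoot; redraw
    covered[hit] <- TRUE
    porosity <- new_por
    px <- c(px, x); py <- c(py, y); pz <- c(pz, z); dum <- c(dum, d_um)
  }

  structure(list(spec = spec, anchor_radius = anchor_radius,
                 slice_thickness = slice_thickness, bone_layer = bone_layer,
                 dim = dim,
                 pores = data.frame(x = px, y = py, z = pz, diameter = dum),
                 achieved_porosity = porosity, raster = raster),
            class = "porous_domain")
}

# indices of raster/mesh cells whose centroid lies inside a ball, using a
# bounding-box subgrid so large grids stay cheap
.cells_in_ball <- function(grid, px, py, pz, rad) {
  s <- grid$s
  ilo <- max(1L, floor((px - rad) / s) + 1L)
  ihi <- min(grid$nx, ceiling((px + rad) / s))
  jlo <- max(1L, floor((py - rad) / s) + 1L)
  jhi <- min(grid$nx, ceiling((py + rad) / s))
  if (ihi < ilo || jhi < jlo) return(integer(0))
  if (grid$dim == 3) {
    klo <- max(1L, floor((pz - rad) / s) + 1L)
    khi <- min(grid$nz, ceiling((pz + rad) / s))
    if (khi < klo) return(integer(0))
    ii <- rep(ilo:ihi, times = (jhi - jlo + 1L) * (khi - klo + 1L))
    jj <- rep(rep(jlo:jhi, each = ihi - ilo + 1L), times = khi - klo + 1L)
    kk <- rep(klo:khi, each = (ihi - ilo + 1L) * (jhi - jlo + 1L))
  } else {
    ii <- rep(ilo:ihi, times = jhi - jlo + 1L)
    jj <- rep(jlo:jhi, each = ihi - ilo + 1L)
    kk <- rep(1L, length(ii))
  }
  rows <- grid$lookup[ii + (jj - 1L) * grid$nx + (kk - 1L) * grid$nx^2]
  rows <- rows[rows > 0L]
  if (length(rows) == 0) return(integer(0))
  d2 <- (grid$cx[rows] - px)^2 + (grid$cy[rows] - py)^2
  if (grid$dim == 3) d2 <- d2 + (grid$cz[rows] - pz)^2
  rows[d2 <= rad^2]
}

#' @export
print.porous_domain <- function(x, ...) {
  cat(sprintf(paste0("<porous_domain> %dD quarter slice, anchor r = %g mm, ",
                     "bone layer %g mm\n  %d pores (%g +/- %g um), achieved ",
                     "porosity %.3f (target %.2f)\n"),
              x$dim, x$anchor_radius, x$bone_layer, nrow(x$pores),
              x$spec$mean_diameter, x$spec$half_band, x$achieved_porosity,
              x$spec$target_porosity))
  invisible(x)
}

#' Write the pore list of a domain as CSV
#'
#' Columns: x, y, z (mm) and diameter (um).
#'
#' @param domain A `porous_domain`.
#' @param file Output path.
#' @export
write_pores <- function(domain, file) {
  stopifnot(inherits(domain, "porous_domain"))
  utils::write.csv(domain$pores, file, row.names = FALSE)
  invisible(file)
}
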