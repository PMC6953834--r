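#' Load the percentage-depth-dose model
#'
#' The shipped model parameterises the central-axis depth dose per energy by
#' its standard anchors - surface fraction, R100, R90, R50, practical range
#' Rp (mm water-equivalent) and bremsstrahlung tail - following the familiar
#' electron-beam rules of thumb (R90 ~ E/3.2 cm, R50 ~ E/2.33 cm,
#' Rp ~ E/2 cm), plus the lateral penumbra parameters. Edit the YAML to
#' match a measured beam.
#'
#' @param path YAML file; NULL loads the packaged default.
#' @return a [PDDModel].
#' @export
loadPddModel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pdd_model.yaml", package = "ioertdose")
  cfg <- yaml::read_yaml(path)
  new("PDDModel", energies = cfg$energies, lateral = cfg$lateral)
}

#' Construct a beam specification
#'
#' @param energy_mev nominal electron energy.
#' @param spec an [ApplicatorSpec].
#' @param pose an [ApplicatorPose].
#' @param ssd_mm virtual source distance from the bevel centre (default
#'   1000 mm).
#' @param prescription_gy prescribed dose at the 90% isodose.
#' @export
beamSpec <- function(energy_mev, spec, pose, ssd_mm = 1000,
                     prescription_gy = NA_real_) {
  new("BeamSpec", energy_mev = energy_mev, spec = spec, pose = pose,
      ssd_mm = ssd_mm, prescription_gy = prescription_gy)
}

.pdd_params <- function(model, energy) {
  key <- as.character(energy)
  e <- model@energies[[key]]
  if (is.null(e))
    stop(sprintf("energy %s MeV is not in the PDD model (available: %s)",
                 key, paste(names(model@energies), collapse = ", ")))
  e
}

# monotone-cubic depth-dose curve through the anchors; constant tail beyond
.pdd_fun <- function(model, energy) {
  e <- .pdd_params(model, energy)
  x <- c(0, e$r100, e$r90, e$r50, e$rp, e$rp + 30)
  y <- c(e$surface, 1, 0.9, 0.5, e$tail, e$tail)
  f <- stats::splinefun(x, y, method = "monoH.FC")
  tail_end <- e$rp + 30
  function(z) {
    out <- f(pmin(z, tail_end))
    out[z > tail_end] <- e$tail
    pmin(pmax(out, 0), 1)
  }
}

#' Central-axis percentage depth dose
#'
#' Monotone rise from the surface fraction to 1.0 at R100, monotone fall
#' through (R90, 0.9) and (R50, 0.5) to the bremsstrahlung tail beyond the
#' practical range; piecewise-cubic and continuous.
#'
#' @param model a [PDDModel].
#' @param energy energy in MeV (must be tabulated in the model).
#' @param z_we water-equivalent depth(s), mm, >= 0.
#' @return dose fraction(s) of the depth-dose maximum.
#' @export
pdd <- function(model, energy, z_we) {
  stopifnot(all(z_we >= 0))
  .pdd_fun(model, energy)(z_we)
}

#' Lateral beam profile factor
#'
#' Error-function edge: ~1 well inside the divergently projected aperture,
#' 0.5 exactly at its edge, rolling off with
#' sigma = sigma0 + k_we * z_we + k_geo * z_geo. The geometric term carries
#' the penumbra broadening across an air gap, where almost no
#' water-equivalent depth accumulates.
#'
#' @param r off-axis distance(s), mm, >= 0.
#' @param z_we water-equivalent depth, mm.
#' @param aperture_radius divergently projected aperture radius at the
#'   point's depth, mm.
#' @param model a [PDDModel] (its `lateral` parameters are used).
#' @param z_geo geometric path beyond the bevel plane, mm (default `z_we`).
#' @return fraction(s) in [0, 1].
#' @export
lateralFactor <- function(r, z_we, aperture_radius, model, z_geo = z_we) {
  stopifnot(all(r >= 0))
  lt <- model@lateral
  sigma <- lt$sigma0_mm + lt$k_we * z_we + lt$k_geo * z_geo
  stats::pnorm((aperture_radius - r) / sigma)
}

#' Radiological (water-equivalent) depth of points in a beam
#'
#' Line integral of physical density along the ray from the virtual source
#' to each point, starting at the ray's bevel-plane crossing; trilinear
#' density sampling with steps no larger than half the smallest voxel.
#'
#' @param density a [DensityVolume].
#' @param points N x 3 world matrix (or a length-3 vector), mm; all points
#'   must lie distal to the bevel plane.
#' @param beam a [BeamSpec].
#' @param step_mm integration step; default half the smallest spacing.
#' @return mm water-equivalent, one value per point.
#' @export
radiologicalDepth <- function(density, points, beam, step_mm = NULL) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  geom <- applicatorGeometry(beam@spec, beam@pose)
  co <- .applicator_coords(geom, points)
  if (any(co$b <= 0))
    stop("all points must lie distal to the bevel plane")
  if (is.null(step_mm)) step_mm <- min(density@spacing) / 2
  src <- geom$c - beam@ssd_mm * geom$a
  cpp_ray_wepl(density@values, dim(density@values), density@spacing,
               density@origin, src, geom$c, geom$n, points, step_mm,
               outside_density = 0.00121)
}

#' Compute a 3D relative electron dose distribution
#'
#' Divergent pencil-beam engine: for every voxel distal to the bevel plane,
#' dose = PDD(water-equivalent depth) x lateral edge factor x inverse-square
#' (virtual source at `ssd_mm` proximal to the bevel centre), normalised so
#' the grid maximum is 100. Voxels proximal to the bevel plane, or further
#' than `lateral_margin_mm` outside the projected aperture, are 0.
#' Deterministic; any callable honouring this contract can substitute for it
#' in the pipeline (`dose_engine` argument of [runCase()]).
#'
#' @param ct a scenario [CTVolume] on the analysis grid.
#' @param beam a [BeamSpec].
#' @param model a [PDDModel].
#' @param hu_table HU-to-density calibration from [loadHuDensityTable()].
#' @param lateral_margin_mm cutoff beyond the projected aperture (the erf
#'   edge is numerically 0 well inside this margin).
#' @param step_mm ray-integration step.
#' @return a [DoseGrid] (percent of its own maximum).
#' @export
computeDose <- function(ct, beam, model, hu_table = loadHuDensityTable(),
                        lateral_margin_mm = 25, step_mm = NULL) {
  geom <- applicatorGeometry(beam@spec, beam@pose)
  dens <- huToDensity(ct, hu_table)
  w <- voxelCentres(ct)
  co <- .applicator_coords(geom, w)
  src <- geom$c - beam@ssd_mm * geom$a
  u <- sweep(w, 2, src, "-")
  d_ax <- as.numeric(u %*% geom$a)            # axial distance from source
  r_off2 <- pmax(rowSums(u^2) - d_ax^2, 0)
  r_proj <- geom$r_in * d_ax / beam@ssd_mm    # divergent aperture radius
  sel <- co$b > 0 & r_off2 <= (r_proj + lateral_margin_mm)^2 & d_ax > 0
  if (!any(sel)) stop("beam does not intersect the volume distal to the bevel plane")
  if (is.null(step_mm)) step_mm <- min(ct@spacing) / 2
  pts <- w[sel, , drop = FALSE]
  z_we <- cpp_ray_wepl(dens@values, dim(dens@values), dens@spacing,
                       dens@origin, src, geom$c, geom$n, pts, step_mm,
                       outside_density = 0.00121)
  # geometric path beyond the bevel plane along each ray
  nu <- as.numeric(sweep(pts, 2, src, "-") %*% geom$n)
  ncs <- sum(geom$n * (geom$c - src))
  dist_src <- sqrt(rowSums(sweep(pts, 2, src, "-")^2))
  z_geo <- pmax(dist_src * (1 - ncs / nu), 0)
  depth_dose <- pdd(model, beam@energy_mev, z_we)
  lat <- lateralFactor(sqrt(r_off2[sel]), z_we, r_proj[sel], model,
                       z_geo = z_geo)
  invsq <- (beam@ssd_mm / dist_src)^2
  dose <- numeric(nrow(w))
  dose[sel] <- depth_dose * lat * invsq
  mx <- max(dose)
  if (mx <= 0) stop("computed dose is identically zero")
  arr <- array(dose / mx * 100, dim(ct@values))
  new("DoseGrid", values = arr, spacing = ct@spacing, origin = ct@origin,
      orientation = ct@orientation,
      meta = list(scenario = NA_character_, energy_mev = beam@energy_mev,
                  max_raw = mx))
}

#' Scale a relative dose to absolute Gy
#'
#' Gy = dose% x prescription / 90, so a voxel at the 90% isodose receives
#' exactly the prescribed dose.
#'
#' @param dose a [DoseGrid] (percent of maximum).
#' @param prescription_gy prescribed dose at the 90% isodose.
#' @return a 3D array of Gy.
#' @export
absoluteScale <- function(dose, prescription_gy) {
  dose@values * prescription_gy / 90
}
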