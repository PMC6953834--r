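#' Run an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded helpers do not
#' perturb the global stream.
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configure a synthetic pre/intraoperative CT phantom
#'
#' Defaults define the package's reference study conditions: a torso-like
#' ellipsoidal body of soft tissue (40 HU) with two rod-shaped bone
#' structures (900 HU) flanking the treatment volume, a post-resection
#' cavity with an irregular floor carved into the upper surface, a posed
#' PMMA applicator standing off the cavity floor by a target maximum air
#' gap, a small rigid inter-acquisition motion, and 15 HU Gaussian noise.
#'
#' @param dim grid size in voxels.
#' @param spacing voxel size, mm (isotropic 1.5 by default, matching the
#'   analysis grid).
#' @param body_halfaxes,body_centre ellipsoid geometry, mm.
#' @param flat_top,flat_top_z optionally truncate the body by the plane
#'   z = flat_top_z, giving a flat interface on which a 0-degree bevel can
#'   seat with an exactly zero air gap.
#' @param tissue_hu,bone_hu,n_bones,bone_radius_mm,bone_offset_mm,bone_z_mm
#'   tissue/bone CT values and bone rod geometry.
#' @param lowdens_hu optional low-density region HU (NA = none).
#' @param lowdens_centre,lowdens_radius_mm geometry of that region.
#' @param cavity_centre_xy,cavity_radius_mm,cavity_depth_mm footprint centre
#'   (mm, on the body top), footprint radius and base depth of the cavity;
#'   depth 0 suppresses the cavity.
#' @param irregularity_mm amplitude of the band-limited floor perturbation.
#' @param n_bumps number of Gaussian bumps composing the perturbation.
#' @param fluid_depth_mm,fluid_hu optional fluid pool flat-filling the cavity
#'   bottom up to this depth above the deepest point.
#' @param spec an [ApplicatorSpec].
#' @param tilt_deg numeric(2): applicator axis tilt about x and y (degrees)
#'   away from straight down.
#' @param roll_deg bevel roll.
#' @param target_gap_mm target maximum distance from the bevel plane to the
#'   cavity floor along the axis (clinically observed gaps span roughly
#'   8.5-30.5 mm).
#' @param motion_rot_deg,motion_trans_mm rigid inter-acquisition motion
#'   (rotation about the body centre).
#' @param noise_sigma_hu additive Gaussian HU noise.
#' @param seed integer; fixes all randomness.
#' @return a [PhantomConfig].
#' @export
phantomConfig <- function(dim = c(96L, 96L, 128L), spacing = c(1.5, 1.5, 1.5),
                          body_halfaxes = c(62, 55, 48),
                          body_centre = c(0, 0, -10),
                          flat_top = FALSE, flat_top_z = 30,
                          tissue_hu = 40, bone_hu = 900, n_bones = 2L,
                          bone_radius_mm = 8, bone_offset_mm = 40,
                          bone_z_mm = -25,
                          lowdens_hu = NA_real_,
                          lowdens_centre = c(20, -15, -30),
                          lowdens_radius_mm = 8,
                          cavity_centre_xy = c(0, 0), cavity_radius_mm = 30,
                          cavity_depth_mm = 16, irregularity_mm = 6,
                          n_bumps = 6L,
                          fluid_depth_mm = 0, fluid_hu = 10,
                          spec = applicatorSpec(5, 30),
                          tilt_deg = c(8, -5), roll_deg = 40,
                          target_gap_mm = 15,
                          motion_rot_deg = c(3, -2, 4),
                          motion_trans_mm = c(4, -3, 5),
                          noise_sigma_hu = 15, seed = 1L) {
  new("PhantomConfig", dim = as.integer(dim), spacing = as.numeric(spacing),
      body_halfaxes = body_halfaxes, body_centre = body_centre,
      flat_top = flat_top, flat_top_z = flat_top_z,
      tissue_hu = tissue_hu, bone_hu = bone_hu, n_bones = as.integer(n_bones),
      bone_radius_mm = bone_radius_mm, bone_offset_mm = bone_offset_mm,
      bone_z_mm = bone_z_mm, lowdens_hu = lowdens_hu,
      lowdens_centre = lowdens_centre, lowdens_radius_mm = lowdens_radius_mm,
      cavity_centre_xy = cavity_centre_xy, cavity_radius_mm = cavity_radius_mm,
      cavity_depth_mm = cavity_depth_mm, irregularity_mm = irregularity_mm,
      n_bumps = as.integer(n_bumps), fluid_depth_mm = fluid_depth_mm,
      fluid_hu = fluid_hu, spec = spec, tilt_deg = tilt_deg,
      roll_deg = roll_deg, target_gap_mm = target_gap_mm,
      motion_rot_deg = motion_rot_deg, motion_trans_mm = motion_trans_mm,
      noise_sigma_hu = noise_sigma_hu, seed = as.integer(seed))
}

#' Cavity floor surface function
#'
#' Builds the tumour-bed floor as a spherical-cap base of the given footprint
#' radius and centre depth, minus a seeded sum of 2D Gaussian bumps windowed
#' to vanish at the rim and scaled so the largest perturbation equals
#' `amplitude_mm`. Returned as a closure z_floor(x, y) (world mm); the same
#' function is the ground-truth oracle for air-gap depth checks.
#'
#' @param centre_xy footprint centre, mm.
#' @param rim_z world z of the cavity rim plane.
#' @param depth_mm base depth at the footprint centre.
#' @param radius_mm footprint radius.
#' @param amplitude_mm perturbation amplitude (0 = smooth cap).
#' @param n_bumps number of Gaussian bumps.
#' @param seed RNG seed for bump placement.
#' @return function(x, y) -> floor z (vectorised); `rim_z` outside the
#'   footprint.
#' @export
cavityFloorFun <- function(centre_xy, rim_z, depth_mm, radius_mm,
                           amplitude_mm = 0, n_bumps = 6L, seed = 1L) {
  if (depth_mm < 0) stop("cavity depth must be >= 0")
  rc <- radius_mm; d0 <- depth_mm
  if (d0 > 0) {
    Rs <- (rc^2 + d0^2) / (2 * d0)
    zs <- rim_z - d0 + Rs
  }
  bumps <- NULL
  scale <- 0
  if (amplitude_mm > 0 && n_bumps > 0) {
    bumps <- .with_seed(seed, {
      ang <- stats::runif(n_bumps, 0, 2 * pi)
      rad <- rc * 0.75 * sqrt(stats::runif(n_bumps))
      list(x = centre_xy[1] + rad * cos(ang),
           y = centre_xy[2] + rad * sin(ang),
           amp = stats::runif(n_bumps, -1, 1),
           sigma = rc / 3)
    })
    # scale so the windowed perturbation attains the requested amplitude
    gx <- seq(centre_xy[1] - rc, centre_xy[1] + rc, length.out = 121)
    gy <- seq(centre_xy[2] - rc, centre_xy[2] + rc, length.out = 121)
    gg <- expand.grid(x = gx, y = gy)
    raw <- .bump_field(gg$x, gg$y, bumps) *
      .rim_window(gg$x, gg$y, centre_xy, rc)
    m <- max(abs(raw))
    scale <- if (m > 0) amplitude_mm / m else 0
  }
  function(x, y) {
    r2 <- (x - centre_xy[1])^2 + (y - centre_xy[2])^2
    inside <- r2 <= rc^2
    base <- rep(rim_z, length(x))
    if (d0 > 0)
      base[inside] <- zs - sqrt(pmax(Rs^2 - r2[inside], 0))
    if (!is.null(bumps)) {
      pert <- .bump_field(x[inside], y[inside], bumps) *
        .rim_window(x[inside], y[inside], centre_xy, rc) * scale
      base[inside] <- pmin(base[inside] - pert, rim_z)
    }
    base
  }
}

.bump_field <- function(x, y, bumps) {
  out <- numeric(length(x))
  for (i in seq_along(bumps$x))
    out <- out + bumps$amp[i] *
      exp(-((x - bumps$x[i])^2 + (y - bumps$y[i])^2) / (2 * bumps$sigma^2))
  out
}

.rim_window <- function(x, y, centre_xy, rc) {
  r <- sqrt((x - centre_xy[1])^2 + (y - centre_xy[2])^2)
  w <- cos(pi * pmin(r / rc, 1) / 2)^2
  w
}

# Anatomy membership functions in the intraoperative frame (no cavity or
# applicator): pts is an N x 3 world matrix.
.scene_body <- function(pts, cfg) {
  u <- sweep(pts, 2, cfg@body_centre, "-")
  inside <- (u[, 1] / cfg@body_halfaxes[1])^2 +
            (u[, 2] / cfg@body_halfaxes[2])^2 +
            (u[, 3] / cfg@body_halfaxes[3])^2 <= 1
  if (cfg@flat_top) inside <- inside & pts[, 3] <= cfg@flat_top_z
  inside
}

.scene_bone <- function(pts, cfg) {
  out <- rep(FALSE, nrow(pts))
  if (cfg@n_bones < 1) return(out)
  xs <- if (cfg@n_bones == 1) 0 else
    seq(-cfg@bone_offset_mm, cfg@bone_offset_mm, length.out = cfg@n_bones)
  half_len <- 0.65 * cfg@body_halfaxes[2]
  for (x0 in xs) {
    d2 <- (pts[, 1] - x0)^2 + (pts[, 3] - cfg@bone_z_mm)^2
    out <- out | (d2 <= cfg@bone_radius_mm^2 & abs(pts[, 2]) <= half_len)
  }
  out & .scene_body(pts, cfg)
}

.scene_lowdens <- function(pts, cfg) {
  if (is.na(cfg@lowdens_hu)) return(rep(FALSE, nrow(pts)))
  u <- sweep(pts, 2, cfg@lowdens_centre, "-")
  rowSums(u^2) <= cfg@lowdens_radius_mm^2 & .scene_body(pts, cfg)
}

# body-surface z at the cavity centre (rim plane height)
.body_top_z <- function(cfg) {
  u <- cfg@cavity_centre_xy - cfg@body_centre[1:2]
  s <- 1 - (u[1] / cfg@body_halfaxes[1])^2 - (u[2] / cfg@body_halfaxes[2])^2
  if (s <= 0) stop("cavity centre lies outside the body footprint")
  z <- cfg@body_centre[3] + cfg@body_halfaxes[3] * sqrt(s)
  if (cfg@flat_top) min(z, cfg@flat_top_z) else z
}

# Applicator pose implied by a config: axis tilted from straight down,
# lateral anchor at the cavity centre, standoff solved so the maximum
# bevel-plane-to-floor distance along the axis equals target_gap_mm.
.phantom_pose <- function(cfg, floor_fun, rim_z) {
  a <- c(0, 0, -1)
  a <- as.numeric(.rot_axis(c(1, 0, 0), cfg@tilt_deg[1]) %*% a)
  a <- as.numeric(.rot_axis(c(0, 1, 0), cfg@tilt_deg[2]) %*% a)
  a <- a / sqrt(sum(a^2))
  anchor <- c(cfg@cavity_centre_xy, rim_z)
  pose0 <- applicatorPose(anchor, a, roll_deg = cfg@roll_deg,
                          roll_undefined = cfg@spec@bevel_deg == 0)
  geom <- applicatorGeometry(cfg@spec, pose0)
  gap0 <- .floor_max_gap(geom, floor_fun, cfg)
  centre <- anchor + (gap0 - cfg@target_gap_mm) * a
  applicatorPose(centre, a, roll_deg = cfg@roll_deg,
                 roll_undefined = cfg@spec@bevel_deg == 0)
}

# max over the in-aperture floor surface of the signed axial distance from
# the bevel plane (distal positive); fine lateral sampling of the footprint
.floor_max_gap <- function(geom, floor_fun, cfg, step = 0.25) {
  rc <- cfg@cavity_radius_mm
  gx <- seq(cfg@cavity_centre_xy[1] - rc, cfg@cavity_centre_xy[1] + rc,
            by = step)
  gy <- seq(cfg@cavity_centre_xy[2] - rc, cfg@cavity_centre_xy[2] + rc,
            by = step)
  gg <- as.matrix(expand.grid(x = gx, y = gy))
  p <- cbind(gg, floor_fun(gg[, 1], gg[, 2]))
  co <- .applicator_coords(geom, p)
  sel <- co$rho < geom$r_in
  if (!any(sel)) stop("applicator aperture does not project onto the cavity floor")
  max(co$b[sel] / sum(geom$n * geom$a))
}

#' Generate a paired pre/intraoperative CT phantom
#'
#' Renders both volumes analytically (no interpolation) so every truth
#' element is exact: the preoperative scan shows the intact anatomy moved by
#' the inverse of the configured inter-acquisition motion; the intraoperative
#' scan shows the same anatomy with the cavity carved, the applicator in
#' place and the air gap realised by standing the applicator off the cavity
#' floor along its axis. Deterministic given `cfg@seed`.
#'
#' @param cfg a [PhantomConfig].
#' @return a [PhantomCase]; `truth` holds pose, motion, masks
#'   (air_gap, applicator_wall, bone, bone_pre, body, cavity), the floor
#'   closure `floor_fun`, `rim_z` and the analytic `gap_mm`.
#' @export
generatePhantom <- function(cfg) {
  d <- cfg@dim; sp <- cfg@spacing
  org <- -(d - 1) * sp / 2
  grid <- CTVolume(array(0, d), spacing = sp, origin = org)
  pts <- voxelCentres(grid)

  rim_z <- .body_top_z(cfg)
  has_cavity <- cfg@cavity_depth_mm > 0 || cfg@irregularity_mm > 0
  floor_fun <- cavityFloorFun(cfg@cavity_centre_xy, rim_z,
                              cfg@cavity_depth_mm, cfg@cavity_radius_mm,
                              cfg@irregularity_mm, cfg@n_bumps,
                              seed = cfg@seed * 13L + 7L)
  pose <- .phantom_pose(cfg, floor_fun, rim_z)
  geom <- applicatorGeometry(cfg@spec, pose)
  truth_gap <- .floor_max_gap(geom, floor_fun, cfg)

  # ---- intraoperative volume -------------------------------------------
  body <- .scene_body(pts, cfg)
  bone <- .scene_bone(pts, cfg)
  lowd <- .scene_lowdens(pts, cfg)
  hu <- rep(-1000, nrow(pts))
  hu[body] <- cfg@tissue_hu
  hu[bone] <- cfg@bone_hu
  hu[lowd] <- cfg@lowdens_hu

  r2 <- (pts[, 1] - cfg@cavity_centre_xy[1])^2 +
        (pts[, 2] - cfg@cavity_centre_xy[2])^2
  in_fp <- r2 <= cfg@cavity_radius_mm^2
  cavity <- rep(FALSE, nrow(pts))
  if (has_cavity) {
    fl <- rep(rim_z, nrow(pts))
    fl[in_fp] <- floor_fun(pts[in_fp, 1], pts[in_fp, 2])
    cavity <- in_fp & body & pts[, 3] > fl
    hu[cavity] <- -1000
  }
  fluid <- rep(FALSE, nrow(pts))
  if (cfg@fluid_depth_mm > 0 && any(cavity)) {
    z_fill <- min(fl[in_fp]) + cfg@fluid_depth_mm
    fluid <- cavity & pts[, 3] <= z_fill
    hu[fluid] <- cfg@fluid_hu
  }
  co <- .applicator_coords(geom, pts)
  wall <- co$rho >= geom$r_in & co$rho <= geom$r_out & co$b <= 0 &
    co$h >= -geom$length
  if (!any(wall)) stop("applicator pose places no wall voxels inside the volume")
  hu[wall] <- cfg@spec@wall_hu

  body_truth <- (body & !cavity) | fluid
  ext <- co$rho < geom$r_in & co$b > 0 & co$h <= 80
  gap_truth <- ext & !body_truth & in_fp
  if (has_cavity) {
    gap_truth <- gap_truth & pts[, 3] > fl
  } else {
    gap_truth <- gap_truth & pts[, 3] > rim_z
  }

  intra <- array(hu, d)

  # ---- preoperative volume: intact anatomy at motion-mapped coordinates --
  motion <- rtFromEuler(cfg@motion_rot_deg, cfg@motion_trans_mm,
                        centre = cfg@body_centre)
  pts_pre <- rtApply(motion, pts)
  body_p <- .scene_body(pts_pre, cfg)
  bone_p <- .scene_bone(pts_pre, cfg)
  lowd_p <- .scene_lowdens(pts_pre, cfg)
  hu_p <- rep(-1000, nrow(pts))
  hu_p[body_p] <- cfg@tissue_hu
  hu_p[bone_p] <- cfg@bone_hu
  hu_p[lowd_p] <- cfg@lowdens_hu
  pre <- array(hu_p, d)

  if (cfg@noise_sigma_hu > 0) {
    intra <- intra + .with_seed(cfg@seed * 2L + 1L,
      array(stats::rnorm(length(intra), 0, cfg@noise_sigma_hu), d))
    pre <- pre + .with_seed(cfg@seed * 2L + 2L,
      array(stats::rnorm(length(pre), 0, cfg@noise_sigma_hu), d))
  }

  mk <- function(v) Mask(array(v, d), spacing = sp, origin = org)
  new("PhantomCase",
      preop = CTVolume(pre, spacing = sp, origin = org),
      intraop = CTVolume(intra, spacing = sp, origin = org),
      truth = list(pose = pose, motion = motion,
                   air_gap = mk(gap_truth), applicator_wall = mk(wall),
                   bone = mk(bone), bone_pre = mk(bone_p),
                   body = mk(body_truth), cavity = mk(cavity),
                   floor_fun = floor_fun, rim_z = rim_z,
                   gap_mm = truth_gap),
      config = cfg)
}

#' Carve an irregular cavity into a volume
#'
#' Standalone volume edit sharing the floor model of [cavityFloorFun()]:
#' voxels inside the footprint, above the perturbed floor and at or below
#' the rim plane are set to air (-1000 HU).
#'
#' @param vol a [CTVolume].
#' @param centre world position (mm) of the footprint centre on the surface;
#'   centre[3] is the rim-plane height.
#' @param depth_mm base depth at the centre.
#' @param amplitude_mm floor irregularity amplitude.
#' @param seed RNG seed.
#' @param radius_mm footprint radius.
#' @param n_bumps number of Gaussian bumps.
#' @return list(volume = carved [CTVolume], mask = cavity [Mask],
#'   floor_fun = the floor closure).
#' @export
carveCavity <- function(vol, centre, depth_mm, amplitude_mm = 0, seed = 1L,
                        radius_mm = 25, n_bumps = 6L) {
  w <- voxelCentres(vol)
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  if (centre[1] - radius_mm < lo[1] || centre[1] + radius_mm > hi[1] ||
      centre[2] - radius_mm < lo[2] || centre[2] + radius_mm > hi[2] ||
      centre[3] - depth_mm - amplitude_mm < lo[3] || centre[3] > hi[3])
    stop("cavity breaches the volume bounds")
  fl_fun <- cavityFloorFun(centre[1:2], centre[3], depth_mm, radius_mm,
                           amplitude_mm, n_bumps, seed)
  r2 <- (w[, 1] - centre[1])^2 + (w[, 2] - centre[2])^2
  sel <- r2 <= radius_mm^2
  fl <- rep(centre[3], nrow(w))
  fl[sel] <- fl_fun(w[sel, 1], w[sel, 2])
  mask <- sel & w[, 3] > fl & w[, 3] <= centre[3]
  vals <- vol@values
  vals[array(mask, dim(vals))] <- -1000
  list(volume = .new_like("CTVolume", vals, vol),
       mask = Mask(array(mask, dim(vals)), like = vol),
       floor_fun = fl_fun)
}

#' Render an applicator wall into a volume
#'
#' Sets hollow-cylinder wall voxels (between the inner and outer radius,
#' proximal to the bevel plane, within the tube length) to the PMMA wall HU;
#' the interior is left untouched.
#'
#' @param vol a [CTVolume].
#' @param spec an [ApplicatorSpec].
#' @param pose an [ApplicatorPose].
#' @return list(volume = edited [CTVolume], mask = wall [Mask]).
#' @export
placeApplicator <- function(vol, spec, pose) {
  if (spec@wall_mm < min(vol@spacing))
    warning("applicator wall is thinner than one voxel; the rendered wall may be fragmentary")
  geom <- applicatorGeometry(spec, pose)
  w <- voxelCentres(vol)
  co <- .applicator_coords(geom, w)
  wall <- co$rho >= geom$r_in & co$rho <= geom$r_out & co$b <= 0 &
    co$h >= -geom$length
  if (!any(wall))
    stop("applicator pose does not intersect the volume")
  vals <- vol@values
  vals[array(wall, dim(vals))] <- spec@wall_hu
  list(volume = .new_like("CTVolume", vals, vol),
       mask = Mask(array(wall, dim(vals)), like = vol))
}

#' Add Gaussian HU noise
#'
#' @param vol a [CTVolume].
#' @param sigma_hu noise standard deviation (HU); 0 returns the input.
#' @param seed RNG seed.
#' @export
addNoise <- function(vol, sigma_hu, seed = 1L) {
  stopifnot(sigma_hu >= 0)
  if (sigma_hu == 0) return(vol)
  d <- dim(vol@values)
  noise <- .with_seed(seed, array(stats::rnorm(prod(d), 0, sigma_hu), d))
  .new_like("CTVolume", vol@values + noise, vol)
}
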