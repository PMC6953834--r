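#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation numeric(3), mm.
#' @return a [RigidTransform] mapping moving-frame world coordinates into the
#'   fixed frame.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Identity transform
#' @export
rtIdentity <- function() rigidTransform()

.rot_axis <- function(axis, deg) {
  th <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rigid transform from Euler angles
#'
#' Rotations are applied in x, then y, then z order about `centre`;
#' `translation` is added afterwards, so
#' x' = R (x - centre) + centre + translation.
#'
#' @param rot_deg numeric(3) rotations about the x/y/z axes (degrees).
#' @param translation numeric(3) mm.
#' @param centre rotation centre (mm), default the world origin.
#' @export
rtFromEuler <- function(rot_deg = c(0, 0, 0), translation = c(0, 0, 0),
                        centre = c(0, 0, 0)) {
  R <- .rot_axis(c(0, 0, 1), rot_deg[3]) %*%
       .rot_axis(c(0, 1, 0), rot_deg[2]) %*%
       .rot_axis(c(1, 0, 0), rot_deg[1])
  t <- as.numeric(centre) - R %*% as.numeric(centre) + as.numeric(translation)
  rigidTransform(R, t)
}

#' Compose two rigid transforms
#'
#' `rtCompose(a, b)` applies `b` first, then `a`.
#' @param a,b [RigidTransform]s.
#' @export
rtCompose <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param t a [RigidTransform].
#' @export
rtInvert <- function(t) {
  Rt <- t(t@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% t@translation))
}

#' Apply a rigid transform to points
#'
#' @param t a [RigidTransform].
#' @param pts N x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @return transformed points, same shape.
#' @export
rtApply <- function(t, pts) {
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, 1)
  out <- sweep(pts %*% t(t@rotation), 2, t@translation, "+")
  if (single) drop(out) else out
}

#' Resample a volume onto a reference grid through a rigid transform
#'
#' The transform maps the moving volume's world frame into the fixed
#' (reference) frame; output voxel values are sampled at the inverse-mapped
#' positions with trilinear interpolation (nearest for masks), and points
#' falling outside the moving volume get -1000 HU (0 for masks/dose).
#'
#' @param vol the moving volume.
#' @param t a [RigidTransform] (moving -> fixed).
#' @param reference a volume defining the output grid (default: `vol`).
#' @export
applyTransform <- function(vol, t, reference = vol) {
  inv <- rtInvert(t)
  w <- voxelCentres(reference)
  wm <- rtApply(inv, w)
  idx <- .world_to_index0(vol, wm)
  d_in <- dim(vol@values)
  is_mask <- is(vol, "Mask")
  outside <- if (is(vol, "CTVolume")) -1000 else 0
  src <- vol@values
  if (is.logical(src)) storage.mode(src) <- "double"
  vals <- if (is_mask) cpp_sample_nearest(src, d_in, idx, outside)
          else cpp_sample_trilinear(src, d_in, idx, outside)
  arr <- array(vals, dim(reference@values))
  if (is_mask)
    Mask(arr != 0, spacing = reference@spacing, origin = reference@origin,
         orientation = reference@orientation)
  else
    .new_like(class(vol), arr, reference,
              meta = if (is(vol, "DoseGrid")) vol@meta else NULL)
}

#' Move a volume within its own grid
#'
#' Emulates patient repositioning between acquisitions: the output keeps the
#' input grid, with values resampled through the inverse-mapped coordinates.
#'
#' @inheritParams applyTransform
#' @export
applyRigidMotion <- function(vol, t) applyTransform(vol, t, reference = vol)

#' Write a rigid transform as JSON
#'
#' Stored as 9 row-major rotation entries plus the translation, with the
#' convention string "moving->fixed, LPS mm".
#'
#' @param t a [RigidTransform].
#' @param path output path.
#' @export
writeTransform <- function(t, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(t@rotation)),
                            translation = t@translation,
                            convention = "moving->fixed, LPS mm"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform written by [writeTransform()]
#' @param path JSON path.
#' @export
readTransform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}

#' Construct an applicator specification
#'
#' @param diameter_cm inner (aperture) diameter in cm, as quoted clinically.
#' @param bevel_deg bevel angle in degrees (0-60; clinical set 0/15/30/45).
#' @param wall_mm wall thickness (default 5 mm).
#' @param length_mm tube length proximal of the bevel centre (default 100).
#' @param wall_hu CT value of the PMMA wall (default 120 HU, close to soft
#'   tissue).
#' @export
applicatorSpec <- function(diameter_cm, bevel_deg = 0, wall_mm = 5,
                           length_mm = 100, wall_hu = 120) {
  new("ApplicatorSpec", diameter_mm = diameter_cm * 10,
      bevel_deg = bevel_deg, wall_mm = wall_mm, length_mm = length_mm,
      wall_hu = wall_hu)
}

#' Construct an applicator pose
#'
#' @param bevel_centre world position (mm) of the exit-face centre.
#' @param axis unit vector pointing distally (into tissue).
#' @param roll_deg rotation of the bevel's shorter edge about the axis,
#'   in the canonical basis of [poseBasis()].
#' @param roll_undefined TRUE iff the bevel angle is 0 (rotational symmetry).
#' @export
applicatorPose <- function(bevel_centre, axis, roll_deg = 0,
                           roll_undefined = FALSE) {
  axis <- as.numeric(axis); axis <- axis / sqrt(sum(axis^2))
  new("ApplicatorPose", bevel_centre = as.numeric(bevel_centre), axis = axis,
      roll_deg = roll_deg %% 360, roll_undefined = roll_undefined)
}

#' Canonical in-plane basis perpendicular to an applicator axis
#'
#' e1 is the unit projection of world +x onto the plane normal to the axis
#' (world +y if the axis is nearly parallel to x); e2 = axis x e1. Roll
#' angles are measured from e1 towards e2.
#'
#' @param axis unit 3-vector.
#' @return list(e1, e2).
#' @export
poseBasis <- function(axis) {
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

# Full applicator geometry: basis, bevel-plane normal (pointing distally),
# radii and length. The bevel plane passes through the bevel centre with
# normal n = cos(beta) a + sin(beta) s, where s is the shorter-edge direction
# given by the roll angle.
applicatorGeometry <- function(spec, pose) {
  a <- pose@axis
  b <- poseBasis(a)
  roll <- if (pose@roll_undefined) 0 else pose@roll_deg
  s <- cos(roll * pi / 180) * b$e1 + sin(roll * pi / 180) * b$e2
  beta <- spec@bevel_deg * pi / 180
  n <- cos(beta) * a + sin(beta) * s
  list(a = a, e1 = b$e1, e2 = b$e2, s = s, n = n, c = pose@bevel_centre,
       r_in = spec@diameter_mm / 2,
       r_out = spec@diameter_mm / 2 + spec@wall_mm,
       length = spec@length_mm, beta = beta)
}

# Membership helpers on a point matrix: lateral radius, axial coordinate
# (distal positive) and signed bevel-plane coordinate (distal positive).
.applicator_coords <- function(geom, pts) {
  u <- sweep(pts, 2, geom$c, "-")
  h <- as.numeric(u %*% geom$a)
  lat2 <- rowSums(u^2) - h^2
  lat2[lat2 < 0] <- 0
  list(h = h, rho = sqrt(lat2), b = as.numeric(u %*% geom$n))
}
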