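# Shared fixture builders; everything is generated in code at test time.

dice <- function(a, b) {
  av <- if (is(a, "Mask")) a@values else a
  bv <- if (is(b, "Mask")) b@values else b
  2 * sum(av & bv) / (sum(av) + sum(bv))
}

# compact phantom for unit tests (96 mm cube at 1.5 mm)
small_phantom_config <- function(...) {
  args <- list(dim = c(64L, 64L, 64L), spacing = c(1.5, 1.5, 1.5),
               body_halfaxes = c(42, 38, 34), body_centre = c(0, 0, -6),
               bone_offset_mm = 30, bone_radius_mm = 7, bone_z_mm = -18,
               cavity_radius_mm = 20, cavity_depth_mm = 10,
               irregularity_mm = 4,
               spec = applicatorSpec(3.5, 15), tilt_deg = c(5, -3),
               roll_deg = 40, target_gap_mm = 8,
               motion_rot_deg = c(2, -1, 3), motion_trans_mm = c(3, -2, 4),
               noise_sigma_hu = 0, seed = 1L)
  do.call(phantomConfig, utils::modifyList(args, list(...)))
}

# smooth positive random field in [0, 100] for gamma tests
smooth_dose_field <- function(n, spacing_mm, seed, smooth_mm = 6) {
  set.seed(seed)
  a <- array(rnorm(n^3), c(n, n, n))
  a <- ioertdose:::cpp_gaussian_smooth(a, c(n, n, n),
                                       rep(smooth_mm / spacing_mm, 3))
  a <- array(a, c(n, n, n))
  (a - min(a)) / (max(a) - min(a)) * 100
}

as_dose <- function(arr, spacing_mm) {
  new("DoseGrid", values = arr, spacing = rep(spacing_mm, 3),
      origin = c(0, 0, 0), orientation = diag(3), meta = list())
}

full_mask <- function(arr, spacing_mm) {
  Mask(array(TRUE, dim(arr)), spacing = rep(spacing_mm, 3),
       origin = c(0, 0, 0))
}

# water tank with a horizontal surface near z = surface_z; odd x/y
# dimensions so one voxel column lies exactly on the beam axis. The
# trilinear-effective surface (attribute "surface") is half a voxel above
# the topmost water voxel centre.
water_tank <- function(n = 65, nz = 73, spacing = 1.5, surface_z = 0,
                       hu = 0) {
  org <- c(-(n - 1) / 2 * spacing, -(n - 1) / 2 * spacing,
           -(nz - 1) / 2 * spacing)
  v <- CTVolume(array(-1000, c(n, n, nz)), spacing = rep(spacing, 3),
                origin = org)
  w <- voxelCentres(v)
  arr <- v@values
  water <- w[, 3] < surface_z
  arr[water] <- hu
  v@values <- arr
  attr(v, "surface") <- max(w[water, 3]) + spacing / 2
  v
}

angdiff <- function(a, b) {
  d <- abs(a - b) %% 360
  min(d, 360 - d)
}

pose_error <- function(pose, truth) {
  c(centre = sqrt(sum((pose@bevel_centre - truth@bevel_centre)^2)),
    axis = acos(min(1, sum(pose@axis * truth@axis))) * 180 / pi,
    roll = if (pose@roll_undefined || truth@roll_undefined) NA_real_
           else angdiff(pose@roll_deg, truth@roll_deg))
}

# slow, dependency-free flood fill used as the region-growing oracle
flood_oracle <- function(inwin, seeds, connectivity) {
  d <- dim(inwin)
  cur <- array(FALSE, d)
  for (s in seq_len(nrow(seeds))) cur[seeds[s, 1], seeds[s, 2], seeds[s, 3]] <- TRUE
  cur <- cur & inwin
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nz <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- offs[nz > 0 & (connectivity == 26 | nz == 1), ]
  shift3 <- function(a, dx, dy, dz) {
    out <- array(FALSE, dim(a))
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
    out
  }
  repeat {
    grown <- cur
    for (r in seq_len(nrow(offs)))
      grown <- grown | shift3(cur, offs$dx[r], offs$dy[r], offs$dz[r])
    grown <- grown & inwin
    if (identical(grown, cur)) break
    cur <- grown
  }
  cur
}

# direct trilinear interpolation oracle (R, no clamping subtleties: callers
# pass interior points only)
trilinear_oracle <- function(arr, idx0) {
  d <- dim(arr)
  vapply(seq_len(nrow(idx0)), function(q) {
    p <- idx0[q, ]
    i0 <- floor(p); f <- p - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wgt <- (if (dx) f[1] else 1 - f[1]) * (if (dy) f[2] else 1 - f[2]) *
             (if (dz) f[3] else 1 - f[3])
      acc <- acc + wgt * arr[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    acc
  }, numeric(1))
}
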