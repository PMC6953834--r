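#' Region growing in a Hounsfield window
#'
#' Grows the maximal connected set containing the seeds whose HU values lie
#' in [hu_min, hu_max], optionally intersected with a constraint mask (the
#' reproducible stand-in for manually delineated boundaries). Deterministic;
#' the result is invariant to the choice of seed within one connected
#' component.
#'
#' @param vol a [CTVolume].
#' @param seeds N x 3 matrix of 1-based voxel indices (a single seed may be
#'   given as a length-3 vector).
#' @param hu_min,hu_max HU window (inclusive; -Inf/Inf allowed).
#' @param constraint optional [Mask]; growth never leaves it.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners).
#' @return a [Mask].
#' @export
regionGrow <- function(vol, seeds, hu_min = -Inf, hu_max = Inf,
                       constraint = NULL, connectivity = 6) {
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  stopifnot(ncol(seeds) == 3, connectivity %in% c(6, 26))
  cons <- NULL
  if (!is.null(constraint)) {
    .stopifnot_same_grid(vol, constraint)
    cons <- constraint@values
  }
  d <- dim(vol@values)
  m <- cpp_region_grow(vol@values, d, hu_min, hu_max,
                       matrix(as.integer(seeds) - 1L, ncol = 3),
                       if (is.null(cons)) NULL else cons,
                       as.integer(connectivity))
  Mask(array(m, d), like = vol)
}

#' Segment bone structures
#'
#' Region growing with a lower HU bound (default 200 HU) followed by a
#' morphological closing of 1 voxel.
#'
#' @inheritParams regionGrow
#' @param hu_min lower HU bound of the bone window.
#' @param closing_radius closing radius in voxels.
#' @return a [Mask].
#' @export
segmentBone <- function(vol, seeds, constraint = NULL, hu_min = 200,
                        connectivity = 6, closing_radius = 1) {
  m <- regionGrow(vol, seeds, hu_min = hu_min, hu_max = Inf,
                  constraint = constraint, connectivity = connectivity)
  d <- dim(m@values)
  v <- cpp_morph(cpp_morph(m@values, d, closing_radius, 26L, TRUE),
                 d, closing_radius, 26L, FALSE)
  if (!any(v)) stop("bone segmentation produced an empty mask")
  Mask(array(v, d), like = vol)
}

#' Automatic bone seeds
#'
#' Picks up to `n` well-separated voxels above a confident bone HU value,
#' for pipeline use where no manual seed is supplied.
#' @param vol a [CTVolume].
#' @param hu_min confident bone threshold (default 500 HU).
#' @param n maximum number of seeds.
#' @return an N x 3 matrix of 1-based voxel indices.
#' @export
autoBoneSeeds <- function(vol, hu_min = 500, n = 40) {
  idx <- which(vol@values >= hu_min)
  if (!length(idx)) stop("no voxels above the bone seed threshold")
  pick <- idx[seq(1, length(idx), length.out = min(n, length(idx)))]
  arrayInd(pick, dim(vol@values))
}

# distal extension of the applicator's inner cylinder, as a constraint mask
.gap_constraint <- function(vol, pose, spec, max_extension_mm, margin_mm = 0) {
  geom <- applicatorGeometry(spec, pose)
  w <- voxelCentres(vol)
  co <- .applicator_coords(geom, w)
  t_ax <- co$b / sum(geom$n * geom$a)
  sel <- co$rho < geom$r_in + margin_mm & co$b > 0 & t_ax <= max_extension_mm
  Mask(array(sel, dim(vol@values)), like = vol)
}

#' Segment the air gap under the applicator
#'
#' Region growing of sub-threshold voxels (default HU <= -500) seeded just
#' distal to the bevel plane inside the aperture, constrained to the
#' longitudinal extension of the applicator's inner cylinder. An empty
#' result is a valid zero gap.
#'
#' @param vol intraoperative [CTVolume].
#' @param pose an [ApplicatorPose].
#' @param spec an [ApplicatorSpec].
#' @param constraint optional additional [Mask].
#' @param hu_max air-gap upper HU limit.
#' @param max_extension_mm how far distal of the bevel plane to search.
#' @param connectivity 6 or 26.
#' @return a [Mask] (possibly empty).
#' @export
segmentAirGap <- function(vol, pose, spec, constraint = NULL, hu_max = -500,
                          max_extension_mm = 80, connectivity = 6) {
  ext <- .gap_constraint(vol, pose, spec, max_extension_mm)
  cons_vals <- ext@values
  if (!is.null(constraint)) {
    .stopifnot_same_grid(vol, constraint)
    cons_vals <- cons_vals & constraint@values
  }
  d <- dim(vol@values)
  # seeds: sub-threshold voxels within 2 voxels of the axis, just distal to
  # the bevel centre
  geom <- applicatorGeometry(spec, pose)
  w <- voxelCentres(vol)
  co <- .applicator_coords(geom, w)
  near_axis <- co$rho <= 2 * max(vol@spacing) & co$b > 0 &
    co$b <= 6 * max(vol@spacing)
  cand <- which(near_axis & cons_vals & vol@values <= hu_max)
  if (!length(cand)) {
    # no sub-threshold voxel at the seed position: a valid zero-gap result
    return(Mask(array(FALSE, d), like = vol))
  }
  seeds <- arrayInd(cand[which.min(co$b[cand])], d)
  m <- cpp_region_grow(vol@values, d, -Inf, hu_max,
                       matrix(as.integer(seeds) - 1L, ncol = 3),
                       cons_vals, as.integer(connectivity))
  Mask(array(m, d), like = vol)
}

#' Segment the applicator wall
#'
#' Region growing in a PMMA HU window (default [60, 200]) constrained to a
#' generous tube-shaped neighbourhood of an approximate axis. The hint need
#' only be accurate to a few mm laterally.
#'
#' @param vol a [CTVolume].
#' @param axis_hint list(point =, direction =): a world point on the
#'   approximate axis and its direction.
#' @param spec an [ApplicatorSpec].
#' @param hu_window length-2 HU window of the wall.
#' @param tube_margin_mm how far around the nominal wall radii the
#'   neighbourhood extends.
#' @param connectivity 6 or 26.
#' @return a [Mask] of wall voxels.
#' @export
segmentApplicatorWall <- function(vol, axis_hint, spec,
                                  hu_window = c(60, 200), tube_margin_mm = 10,
                                  connectivity = 6) {
  dirv <- axis_hint$direction / sqrt(sum(axis_hint$direction^2))
  w <- voxelCentres(vol)
  u <- sweep(w, 2, axis_hint$point, "-")
  h <- as.numeric(u %*% dirv)
  lat2 <- pmax(rowSums(u^2) - h^2, 0)
  rho <- sqrt(lat2)
  r_in <- spec@diameter_mm / 2
  r_out <- r_in + spec@wall_mm
  tube <- rho >= r_in - tube_margin_mm & rho <= r_out + tube_margin_mm
  d <- dim(vol@values)
  inwin <- vol@values >= hu_window[1] & vol@values <= hu_window[2]
  cand <- which(tube & inwin & abs(rho - (r_in + spec@wall_mm / 2)) <
                  spec@wall_mm)
  if (!length(cand)) stop("applicator wall segmentation failed: no wall-like voxels near the hint axis")
  seeds <- arrayInd(cand[seq(1, length(cand), length.out = min(200, length(cand)))], d)
  m <- cpp_region_grow(vol@values, d, hu_window[1], hu_window[2],
                       matrix(as.integer(seeds) - 1L, ncol = 3),
                       array(tube, d), as.integer(connectivity))
  # QC: demand at least half the analytic shell volume of a one-diameter
  # length of tube, so speckle can never pass for a wall
  shell_vol <- pi * (r_out^2 - r_in^2) * spec@diameter_mm
  if (sum(m) * prod(vol@spacing) < 0.5 * shell_vol)
    stop("applicator wall segmentation failed: recovered wall is fragmentary")
  Mask(array(m, d), like = vol)
}

#' Patient body mask
#'
#' Threshold at the tissue HU floor (default -300), keep the largest
#' connected component, fill enclosed holes, and optionally remove the
#' applicator wall.
#'
#' @param vol a [CTVolume].
#' @param threshold_hu tissue threshold.
#' @param wall optional wall [Mask] to subtract.
#' @return a [Mask].
#' @export
bodyMask <- function(vol, threshold_hu = -300, wall = NULL) {
  d <- dim(vol@values)
  fg <- vol@values >= threshold_hu
  if (!any(fg)) stop("body mask is empty: no voxels above the tissue threshold")
  lab <- cpp_label_components(array(fg, d), d, 26L)
  tab <- tabulate(lab[lab > 0])
  keep <- lab == which.max(tab)
  # fill holes: anything not reachable from the border through the background
  bg <- array(!keep, d)
  border_bg <- which(bg & .border_mask(d))
  if (length(border_bg)) {
    seeds <- arrayInd(border_bg[seq(1, length(border_bg),
                                    length.out = min(500, length(border_bg)))], d)
    reach <- cpp_region_grow(array(as.double(bg), d), d, 0.5, 1.5,
                             matrix(as.integer(seeds) - 1L, ncol = 3),
                             NULL, 6L)
    filled <- keep | (bg & !reach)
  } else filled <- keep | bg
  if (!is.null(wall)) {
    .stopifnot_same_grid(vol, wall)
    filled <- filled & !wall@values
  }
  Mask(array(filled, d), like = vol)
}

.border_mask <- function(d) {
  m <- array(FALSE, d)
  m[c(1, d[1]), , ] <- TRUE
  m[, c(1, d[2]), ] <- TRUE
  m[, , c(1, d[3])] <- TRUE
  m
}

#' Maximum air-gap distance from the applicator end
#'
#' Maximum over gap voxels of the signed distance from the bevel plane along
#' the applicator axis (distal positive). An empty gap returns 0.
#'
#' @param gap an air-gap [Mask].
#' @param pose an [ApplicatorPose].
#' @param spec an [ApplicatorSpec].
#' @return mm.
#' @export
maxAirGapDistance <- function(gap, pose, spec) {
  idx <- which(gap@values)
  if (!length(idx)) return(0)
  geom <- applicatorGeometry(spec, pose)
  w <- voxelCentres(gap)[idx, , drop = FALSE]
  co <- .applicator_coords(geom, w)
  max(co$b / sum(geom$n * geom$a))
}
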