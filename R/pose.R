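#' Fit the applicator axis from a wall mask
#'
#' Initial axis from the principal direction of the wall voxel coordinates,
#' refined by fitting a line through per-slab ring centroids (slabs of two
#' voxels along the working axis). The sign is chosen distal - towards the
#' tissue side - when the underlying volume is supplied; otherwise the axis
#' keeps a -z orientation.
#'
#' @param wall wall [Mask].
#' @param vol optional [CTVolume] used only to orient the axis distally
#'   (the distal end is surrounded by tumour-bed tissue, the proximal end by
#'   ambient air).
#' @param init_axis optional approximate axis direction; when supplied the
#'   principal-component initialisation is skipped, which makes the fit
#'   robust for walls spanning less than ~2.5 tube diameters axially.
#' @return list(axis = unit 3-vector, point = centreline point mm).
#' @export
fitAxis <- function(wall, vol = NULL, init_axis = NULL) {
  idx <- which(wall@values)
  if (length(idx) < 20) stop("degenerate wall mask: too few voxels for an axis fit")
  w <- voxelCentres(wall)[idx, , drop = FALSE]
  cen <- colMeans(w)
  u <- sweep(w, 2, cen, "-")
  if (is.null(init_axis)) {
    ev <- eigen(crossprod(u) / nrow(u), symmetric = TRUE)
    if (ev$values[1] < 1.2 * ev$values[2])
      stop("degenerate wall mask: no clear principal direction")
    a <- ev$vectors[, 1]
  } else {
    a <- as.numeric(init_axis) / sqrt(sum(init_axis^2))
  }
  # refine: centroids of complete rings along the provisional axis. Slabs
  # cut by the bevel plane or the grid boundary are partial rings whose
  # centroids lie off-axis and must not contribute; the best pass (smallest
  # trimmed centroid residual) wins.
  d <- dim(wall@values)
  ijk <- arrayInd(idx, d)
  at_border <- ijk[, 1] <= 2 | ijk[, 1] >= d[1] - 1 |
               ijk[, 2] <= 2 | ijk[, 2] >= d[2] - 1 |
               ijk[, 3] <= 2 | ijk[, 3] >= d[3] - 1
  best <- list(resid = Inf, axis = a, point = cen)
  for (pass in 1:3) {
    h <- as.numeric(u %*% a)
    br <- seq(min(h) - 1e-6, max(h) + 1e-6, by = 3)
    if (length(br) < 4) break
    grp <- findInterval(h, br)
    bb <- poseBasis(a)
    th <- atan2(as.numeric(u %*% bb$e2), as.numeric(u %*% bb$e1))
    sect <- pmin(floor((th %% (2 * pi)) / (2 * pi) * 12) + 1L, 12L)
    cov <- rowsum(.sector_onehot(sect), grp)
    full <- rowSums(cov > 0) == 12
    nper <- as.numeric(table(grp))
    touches <- as.numeric(rowsum(as.numeric(at_border), grp)) > 0
    keep <- full & nper >= 20 & !touches
    if (sum(keep) < 3) break
    cs <- (rowsum(w, grp) / nper)[keep, , drop = FALSE]
    # trim centroids inconsistent with the line (borderline bevel-cut slabs)
    for (it in 1:3) {
      cc <- colMeans(cs)
      uv <- sweep(cs, 2, cc, "-")
      a2 <- eigen(crossprod(uv) / nrow(uv), symmetric = TRUE)$vectors[, 1]
      hh <- as.numeric(uv %*% a2)
      resid <- sqrt(pmax(rowSums(uv^2) - hh^2, 0))
      ok <- resid <= pmax(0.75, 2 * stats::median(resid))
      if (all(ok) || sum(ok) < 3) break
      cs <- cs[ok, , drop = FALSE]
    }
    if (sum(a2 * a) < 0) a2 <- -a2
    a <- a2
    cen <- cc
    u <- sweep(w, 2, cen, "-")
    rq <- sqrt(mean(resid[ok]^2))
    if (rq < best$resid) best <- list(resid = rq, axis = a, point = cen)
  }
  if (is.finite(best$resid)) { a <- best$axis; cen <- best$point }
  if (sum(a * c(0, 0, -1)) < 0) a <- -a
  if (!is.null(vol)) {
    # orient distally: the end with the larger tissue fraction nearby
    h <- as.numeric(u %*% a)
    wv <- voxelCentres(vol)
    rad <- min(40, (max(h) - min(h)) / 2)
    frac <- vapply(list(cen + max(h) * a, cen + min(h) * a), function(e) {
      nb <- rowSums(sweep(wv, 2, e, "-")^2) <= rad^2
      if (!any(nb)) return(0)
      mean(vol@values[nb] > -300)
    }, numeric(1))
    if (frac[2] > frac[1]) a <- -a
  }
  list(axis = a / sqrt(sum(a^2)), point = cen)
}

.sector_onehot <- function(sect) {
  m <- matrix(0L, length(sect), 12)
  m[cbind(seq_along(sect), sect)] <- 1L
  m
}

#' Locate the bevel plane, centre and roll from the wall rim
#'
#' The distal rim is extracted as the most-distal wall voxel in each of 72
#' angular bins about the axis; a plane is least-squares fitted to the rim
#' (with one trimming pass at 2 mm residual), giving the bevel angle, the
#' bevel centre (rim centroid projected to the plane) and the roll as the
#' angular position of the rim's most-proximal point (the shorter edge).
#' A user-supplied shorter-edge world point overrides the automatic roll,
#' emulating the manual step. The roll is flagged undefined when the fitted
#' rim is planar-normal to the axis (bevel consistent with 0 degrees).
#'
#' @param wall wall [Mask].
#' @param axis unit axis (distal positive) from [fitAxis()].
#' @param spec an [ApplicatorSpec].
#' @param centre_point a point on the axis (from [fitAxis()]).
#' @param n_bins angular bins.
#' @param short_edge_point optional world point marking the shorter edge.
#' @param zero_bevel_deg fitted bevel angles below this are reported as
#'   roll-undefined (default 5 degrees).
#' @return list(bevel_centre, roll_deg, roll_undefined, bevel_angle_deg,
#'   fitted_diameter_mm).
#' @export
locateBevel <- function(wall, axis, spec, centre_point = NULL, n_bins = 72,
                        short_edge_point = NULL, zero_bevel_deg = 5) {
  idx <- which(wall@values)
  if (!length(idx)) stop("empty wall mask")
  w <- voxelCentres(wall)[idx, , drop = FALSE]
  if (is.null(centre_point)) centre_point <- colMeans(w)
  b <- poseBasis(axis)
  u <- sweep(w, 2, centre_point, "-")
  h <- as.numeric(u %*% axis)
  x1 <- as.numeric(u %*% b$e1)
  x2 <- as.numeric(u %*% b$e2)
  theta <- atan2(x2, x1) %% (2 * pi)
  bin <- pmin(floor(theta / (2 * pi) * n_bins) + 1L, n_bins)
  rim <- vapply(seq_len(n_bins), function(bb) {
    sel <- which(bin == bb)
    if (!length(sel)) return(NA_integer_)
    sel[which.max(h[sel])]
  }, integer(1))
  filled <- !is.na(rim)
  if (mean(filled) < 0.75)
    stop(sprintf("incomplete rim: only %.0f%% of angular bins populated",
                 100 * mean(filled)))
  ri <- rim[filled]
  fit_plane <- function(ri) {
    X <- cbind(1, x1[ri], x2[ri])
    stats::lm.fit(X, h[ri])$coefficients
  }
  cf <- fit_plane(ri)
  res <- h[ri] - cbind(1, x1[ri], x2[ri]) %*% cf
  keep <- abs(res) <= pmax(2, 2 * stats::mad(res))
  if (sum(keep) >= 0.5 * length(ri)) cf <- fit_plane(ri[keep])
  beta1 <- cf[2]; beta2 <- cf[3]
  bevel_angle <- atan(sqrt(beta1^2 + beta2^2)) * 180 / pi
  # rim centroid projected to the fitted plane along the axis
  c1 <- mean(x1[ri]); c2 <- mean(x2[ri])
  ch <- cf[1] + beta1 * c1 + beta2 * c2
  bevel_centre <- centre_point + c1 * b$e1 + c2 * b$e2 + as.numeric(ch) * axis
  roll_undefined <- bevel_angle < zero_bevel_deg
  if (!is.null(short_edge_point)) {
    v <- as.numeric(short_edge_point) - bevel_centre
    roll <- (atan2(sum(v * b$e2), sum(v * b$e1)) * 180 / pi) %% 360
    roll_undefined <- FALSE
  } else if (roll_undefined) {
    roll <- 0
  } else {
    # shorter edge: direction of steepest descent of the rim height
    roll <- (atan2(-beta2, -beta1) * 180 / pi) %% 360
  }
  rho <- sqrt(x1[ri]^2 + x2[ri]^2)
  list(bevel_centre = as.numeric(bevel_centre), roll_deg = as.numeric(roll),
       roll_undefined = roll_undefined,
       bevel_angle_deg = as.numeric(bevel_angle),
       fitted_diameter_mm = as.numeric(2 * stats::median(rho) - spec@wall_mm))
}

#' Estimate the full applicator pose from a wall segmentation
#'
#' Composition of [fitAxis()] and [locateBevel()], with a QC warning when
#' the fitted aperture diameter deviates from the specification by more
#' than 10%.
#'
#' @inheritParams fitAxis
#' @param spec an [ApplicatorSpec].
#' @param short_edge_point optional manual shorter-edge world point.
#' @param clean apply a 1-voxel morphological opening to the wall mask
#'   before fitting (removes noise speckle attached to the wall).
#' @return an [ApplicatorPose] (with `fitted_diameter_mm` filled in).
#' @export
estimatePose <- function(wall, spec, vol = NULL, short_edge_point = NULL,
                         init_axis = NULL, clean = TRUE) {
  if (clean) {
    # morphological opening strips noise speckle attached to the wall, which
    # would otherwise be picked as spurious most-distal rim voxels
    d <- dim(wall@values)
    op <- cpp_morph(cpp_morph(wall@values, d, 1L, 6L, FALSE), d, 1L, 6L, TRUE)
    if (sum(op) > 0.25 * sum(wall@values))
      wall <- Mask(array(op, d), like = wall)
  }
  ax <- fitAxis(wall, vol = vol, init_axis = init_axis)
  lb <- locateBevel(wall, ax$axis, spec, centre_point = ax$point,
                    short_edge_point = short_edge_point)
  if (is.finite(lb$fitted_diameter_mm) &&
      abs(lb$fitted_diameter_mm - spec@diameter_mm) > 0.1 * spec@diameter_mm)
    warning(sprintf("fitted aperture diameter %.1f mm deviates >10%% from the %.1f mm specification",
                    lb$fitted_diameter_mm, spec@diameter_mm))
  pose <- applicatorPose(lb$bevel_centre, ax$axis, roll_deg = lb$roll_deg,
                         roll_undefined = lb$roll_undefined)
  pose@fitted_diameter_mm <- lb$fitted_diameter_mm
  pose
}
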