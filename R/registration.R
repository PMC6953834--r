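#' Normalised mutual information over a mask
#'
#' Studholme's normalisation (H(A) + H(B)) / H(A, B) of the joint histogram
#' of two co-gridded volumes, restricted to mask voxels. HU values are
#' clamped to [-1000, 2000] and binned linearly. The range is (1, 2]; two
#' constant images are a degenerate (perfectly dependent) pair and return 2
#' with a warning.
#'
#' @param fixed,moving_warped [CTVolume]s on one grid.
#' @param mask a non-empty [Mask] on the same grid.
#' @param bins number of histogram bins per image.
#' @param clamp HU clamp range.
#' @return scalar NMI.
#' @export
nmi <- function(fixed, moving_warped, mask, bins = 32,
                clamp = c(-1000, 2000)) {
  .stopifnot_same_grid(fixed, moving_warped, mask)
  sel <- mask@values
  if (!any(sel)) stop("NMI is undefined on an empty mask")
  .nmi_values(fixed@values[sel], moving_warped@values[sel], bins, clamp)
}

.nmi_values <- function(a, b, bins, clamp = c(-1000, 2000)) {
  ba <- .hist_bin(a, bins, clamp)
  bb <- .hist_bin(b, bins, clamp)
  joint <- tabulate(ba + bins * (bb - 1L), nbins = bins * bins)
  p <- joint / sum(joint)
  pa <- rowSums(matrix(p, bins))
  pb <- colSums(matrix(p, bins))
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  hab <- -sum(p[p > 0] * log(p[p > 0]))
  if (hab == 0) {
    warning("degenerate joint histogram (constant images); NMI set to 2")
    return(2)
  }
  (ha + hb) / hab
}

.hist_bin <- function(x, bins, clamp) {
  x <- pmin(pmax(x, clamp[1]), clamp[2])
  b <- as.integer(floor((x - clamp[1]) / (clamp[2] - clamp[1]) * bins)) + 1L
  pmin(b, bins)
}

# rigid parameters (rx, ry, rz deg; tx, ty, tz mm), rotating about `centre`
.params_to_transform <- function(par, centre) {
  rtFromEuler(par[1:3], par[4:6], centre = centre)
}

#' Rigid registration by NMI over segmented bone
#'
#' Aligns the preoperative (moving) to the intraoperative (fixed) CT by
#' maximising NMI evaluated at fixed-image bone voxels (mask dilated by 2
#' voxels), sampling the moving image through the current transform with
#' trilinear interpolation. Multi-resolution via Gaussian smoothing of both
#' volumes (4, 2, 1 mm), Nelder-Mead at each level. Deterministic given the
#' initial transform.
#'
#' Both volumes are expected on (near-)isotropic analysis grids, typically
#' 1.5 mm from [resampleIsotropic()].
#'
#' @param fixed intraoperative [CTVolume].
#' @param moving preoperative [CTVolume].
#' @param fixed_bone bone [Mask] on the fixed grid (non-empty).
#' @param init initial [RigidTransform] (moving -> fixed); default identity.
#' @param bins histogram bins.
#' @param smooth_mm multi-resolution smoothing schedule, mm.
#' @param max_samples cap on the number of metric sample voxels.
#' @param bone_hu_min HU used for the initial bone-overlap sanity check.
#' @param min_overlap minimum fraction of fixed bone voxels whose
#'   init-mapped moving HU is bone-like; below this the initialisation is
#'   rejected rather than silently fitted.
#' @param maxit Nelder-Mead iteration cap per level.
#' @return the optimal [RigidTransform] (moving -> fixed), with attributes
#'   `nmi` (final metric) and `convergence`.
#' @export
rigidRegister <- function(fixed, moving, fixed_bone, init = rtIdentity(),
                          bins = 32, smooth_mm = c(4, 2, 1),
                          max_samples = 8000, bone_hu_min = 200,
                          min_overlap = 0.1, maxit = 600) {
  .stopifnot_same_grid(fixed, fixed_bone)
  if (!any(fixed_bone@values)) stop("fixed bone mask is empty")
  d_f <- dim(fixed@values); d_m <- dim(moving@values)

  dil <- cpp_morph(fixed_bone@values, d_f, 2L, 26L, TRUE)
  idx <- which(dil)
  if (length(idx) > max_samples)
    idx <- idx[seq(1, length(idx), length.out = max_samples)]
  w_fix <- voxelCentres(fixed)[idx, , drop = FALSE]
  centre <- colMeans(voxelCentres(fixed)[which(fixed_bone@values), ,
                                         drop = FALSE])

  # initial bone-overlap check on the raw bone mask
  w_bone <- voxelCentres(fixed)[which(fixed_bone@values), , drop = FALSE]
  mvals <- cpp_sample_trilinear(moving@values, d_m,
                                .world_to_index0(moving,
                                                 rtApply(rtInvert(init), w_bone)),
                                -1000)
  overlap <- mean(mvals >= bone_hu_min)
  if (overlap < min_overlap)
    stop(sprintf(paste0("registration initialisation rejected: only %.1f%% of ",
                        "fixed bone voxels map onto bone-like moving HU"),
                 100 * overlap))

  # express init as parameters about `centre`
  par <- .transform_to_params(init, centre)
  conv <- 0L
  val <- NA_real_
  first <- TRUE
  for (sg in smooth_mm) {
    fsm <- if (sg > 0)
      cpp_gaussian_smooth(fixed@values, d_f, sg / fixed@spacing)
    else fixed@values
    msm <- if (sg > 0)
      cpp_gaussian_smooth(moving@values, d_m, sg / moving@spacing)
    else moving@values
    fvals <- array(fsm, d_f)[idx]
    cost <- function(p) {
      tr <- .params_to_transform(p, centre)
      mv <- cpp_sample_trilinear(msm, d_m,
                                 .world_to_index0(moving,
                                                  rtApply(rtInvert(tr), w_fix)),
                                 -1000)
      -.nmi_values(fvals, mv, bins)
    }
    if (first) {
      # coarse translation sweep: pulls the start into the NMI capture
      # basin when the initial bone overlap is marginal
      grid <- expand.grid(tx = seq(-12, 12, by = 4), ty = seq(-12, 12, by = 4),
                          tz = seq(-12, 12, by = 4))
      cvals <- vapply(seq_len(nrow(grid)), function(g)
        cost(par + c(0, 0, 0, grid$tx[g], grid$ty[g], grid$tz[g])),
        numeric(1))
      bestg <- which.min(cvals)
      par <- par + c(0, 0, 0, grid$tx[bestg], grid$ty[bestg], grid$tz[bestg])
      first <- FALSE
    }
    opt <- stats::optim(par, cost, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-9))
    par <- opt$par
    conv <- opt$convergence
    val <- -opt$value
  }
  if (conv != 0)
    stop(sprintf("registration did not converge (optim code %d, NMI %.4f)",
                 conv, val))
  out <- .params_to_transform(par, centre)
  attr(out, "nmi") <- val
  attr(out, "convergence") <- conv
  attr(out, "overlap_init") <- overlap
  out
}

# inverse of .params_to_transform: recover Euler parameters about `centre`
.transform_to_params <- function(t, centre) {
  R <- t@rotation
  # x-y-z intrinsic composition R = Rz Ry Rx
  ry <- asin(pmin(1, pmax(-1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  tr <- t@translation - (as.numeric(centre) - as.numeric(R %*% centre))
  c(c(rx, ry, rz) * 180 / pi, tr)
}
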