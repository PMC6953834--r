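#' Blank the applicator interior to air
#'
#' Sets voxels strictly inside the tube's inner cylinder, proximal to the
#' bevel plane and within the tube length, to -1000 HU - the standard TPS
#' edit before dose calculation. Idempotent; wall voxels are untouched.
#'
#' @param vol a [CTVolume].
#' @param pose an [ApplicatorPose].
#' @param spec an [ApplicatorSpec].
#' @export
blankApplicatorInterior <- function(vol, pose, spec) {
  geom <- applicatorGeometry(spec, pose)
  w <- voxelCentres(vol)
  co <- .applicator_coords(geom, w)
  interior <- co$rho < geom$r_in & co$b <= 0 & co$h >= -geom$length
  vals <- vol@values
  vals[array(interior, dim(vals))] <- -1000
  .new_like("CTVolume", vals, vol)
}

#' Overwrite air-gap voxels with air
#'
#' @param vol a [CTVolume].
#' @param gap a [Mask] on the same grid.
#' @export
applyAirGap <- function(vol, gap) {
  .stopifnot_same_grid(vol, gap)
  vals <- vol@values
  vals[gap@values] <- -1000
  .new_like("CTVolume", vals, vol)
}

#' Replace body voxels with water
#'
#' @param vol a [CTVolume].
#' @param body a body [Mask] on the same grid.
#' @export
waterize <- function(vol, body) {
  .stopifnot_same_grid(vol, body)
  vals <- vol@values
  vals[body@values] <- 0
  .new_like("CTVolume", vals, vol)
}

#' Build the five dose-calculation scenarios
#'
#' From the intraoperative CT, the registered preoperative CT, the segmented
#' air gap, the applicator pose and the preoperative body mask, constructs
#' (all with the applicator interior blanked to air):
#' \describe{
#'   \item{intraCT}{the gold standard - the actual scenario.}
#'   \item{preCT}{registered preoperative CT: heterogeneities, no air gap.}
#'   \item{preCT_air}{preCT with the segmented gap set to air.}
#'   \item{preCT_water}{the conventional assumption - body waterised and a
#'     water half-space starting at the bevel plane (configurable to the
#'     distal-most rim point instead).}
#'   \item{preCT_water_air}{body waterised, then the gap set to air; the gap
#'     edit is applied after waterising, so gap voxels end at -1000 HU.}
#' }
#'
#' @param intra,pre_registered [CTVolume]s on the common analysis grid.
#' @param gap air-gap [Mask].
#' @param pose an [ApplicatorPose].
#' @param spec an [ApplicatorSpec].
#' @param body_pre body [Mask] of the registered preoperative image.
#' @param water_plane "bevel" (default) starts the water half-space at the
#'   bevel plane; "distal_rim" starts it at the plane through the
#'   distal-most rim point normal to the axis.
#' @return a [ScenarioSet].
#' @export
buildScenarios <- function(intra, pre_registered, gap, pose, spec, body_pre,
                           water_plane = c("bevel", "distal_rim")) {
  water_plane <- match.arg(water_plane)
  .stopifnot_same_grid(intra, pre_registered, gap, body_pre)
  intraCT <- blankApplicatorInterior(intra, pose, spec)
  preCT <- blankApplicatorInterior(pre_registered, pose, spec)
  preCT_air <- applyAirGap(preCT, gap)
  pre_w <- waterize(preCT, body_pre)
  preCT_water_air <- applyAirGap(pre_w, gap)

  geom <- applicatorGeometry(spec, pose)
  w <- voxelCentres(intra)
  co <- .applicator_coords(geom, w)
  distal <- if (water_plane == "bevel") co$b > 0 else
    co$h > geom$r_in * tan(geom$beta)
  vals <- pre_w@values
  vals[array(distal, dim(vals))] <- 0
  preCT_water <- .new_like("CTVolume", vals, pre_w)

  new("ScenarioSet", intraCT = intraCT, preCT_water = preCT_water,
      preCT = preCT, preCT_water_air = preCT_water_air, preCT_air = preCT_air,
      provenance = list(water_plane = water_plane,
                        gap_voxels = sum(gap@values)))
}

#' Extract one scenario volume
#'
#' @param x a [ScenarioSet].
#' @param label one of "intraCT", "preCT_water", "preCT", "preCT_water_air",
#'   "preCT_air".
#' @export
scenario <- function(x, label) {
  stopifnot(is(x, "ScenarioSet"))
  label <- match.arg(label, c("intraCT", "preCT_water", "preCT",
                              "preCT_water_air", "preCT_air"))
  slot(x, label)
}

#' Names of the scenario comparisons against the gold standard
#' @export
scenarioComparisons <- function() {
  c("preCT_water", "preCT", "preCT_water_air", "preCT_air")
}
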