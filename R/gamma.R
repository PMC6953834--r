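#' Construct gamma-analysis criteria
#'
#' @param dose_tol_pct dose-difference tolerance, percent of the
#'   normalisation dose (default 3).
#' @param dta_mm distance-to-agreement, mm (default 3).
#' @param threshold_pct reference-dose threshold defining the analysis set
#'   (the classic pair is 10 and 70).
#' @param normalisation "global" (one distribution-wide reference dose) or
#'   "local" (each voxel's own reference dose).
#' @param norm_value explicit normalisation dose; NA uses the reference
#'   distribution's maximum.
#' @param search_radius_mm DTA search radius (default 3 x dta).
#' @param step_frac evaluated-dose sample lattice step as a fraction of the
#'   voxel size (default 1/3), with trilinear dose interpolation.
#' @return a [GammaCriteria].
#' @export
gammaCriteria <- function(dose_tol_pct = 3, dta_mm = 3, threshold_pct = 10,
                          normalisation = "global", norm_value = NA_real_,
                          search_radius_mm = 3 * dta_mm,
                          step_frac = 1 / 3) {
  new("GammaCriteria", dose_tol_pct = dose_tol_pct, dta_mm = dta_mm,
      threshold_pct = threshold_pct, normalisation = normalisation,
      norm_value = norm_value, search_radius_mm = search_radius_mm,
      step_frac = step_frac)
}

.norm_dose <- function(ref, criteria) {
  if (!is.na(criteria@norm_value)) criteria@norm_value else max(ref@values)
}

#' Analysis mask for a gamma comparison
#'
#' Voxels whose reference dose exceeds the threshold percentage of the
#' normalisation dose, intersected with the patient-tissue mask of the
#' gold-standard volume.
#'
#' @param ref reference [DoseGrid].
#' @param tissue tissue [Mask] (voxels outside it are never analysed).
#' @param criteria a [GammaCriteria].
#' @return a [Mask].
#' @export
analysisMask <- function(ref, tissue, criteria = gammaCriteria()) {
  .stopifnot_same_grid(ref, tissue)
  nd <- .norm_dose(ref, criteria)
  sel <- ref@values > criteria@threshold_pct / 100 * nd & tissue@values
  if (!any(sel))
    stop("empty analysis set: no tissue voxel exceeds the dose threshold")
  Mask(sel, like = tissue)
}

.gamma_run <- function(ref, eval, criteria, mask, engine) {
  .stopifnot_same_grid(ref, eval, mask)
  if (max(abs(ref@orientation - diag(3))) > 1e-9)
    stop("gamma analysis requires an axis-aligned grid")
  nd <- .norm_dose(ref, criteria)
  d <- dim(ref@values)
  step <- ref@spacing * criteria@step_frac
  dd_abs <- if (criteria@normalisation == "global")
    criteria@dose_tol_pct / 100 * nd
  else  # local: each voxel's tolerance scales with its own reference dose
    criteria@dose_tol_pct / 100 * pmax(as.numeric(ref@values), 1e-9)
  g <- engine(ref@values, eval@values, d, ref@spacing, mask@values,
              dd_abs, criteria@dta_mm, step, criteria@search_radius_mm)
  garr <- array(g, d)
  analysed <- sum(mask@values)
  passed <- sum(garr[mask@values] <= 1)
  new("GammaResult", gamma = garr, mask = mask,
      pass_rate = 100 * passed / analysed, analysed = analysed,
      passed = passed, criteria = criteria)
}

#' 3D gamma analysis
#'
#' Per analysed reference voxel v, gamma(v) is the minimum over evaluated
#' sample points u within the search radius of
#' sqrt((|v-u| / dta)^2 + ((D_eval(u) - D_ref(v)) / dD)^2), with
#' dD = tolerance% of the normalisation dose (global normalisation), the
#' evaluated dose interpolated trilinearly on a sub-voxel lattice. Sample
#' points outside the evaluated grid are skipped; a voxel whose whole search
#' sphere is outside gets gamma = +Inf. Gamma is asymmetric: the gold
#' standard is always the reference.
#'
#' @param ref reference (gold standard) [DoseGrid].
#' @param eval evaluated [DoseGrid] on the same grid.
#' @param criteria a [GammaCriteria].
#' @param mask analysis [Mask] from [analysisMask()].
#' @return a [GammaResult].
#' @export
gammaMap <- function(ref, eval, criteria = gammaCriteria(),
                     mask = NULL) {
  if (is.null(mask)) stop("an analysis mask is required (see analysisMask())")
  .gamma_run(ref, eval, criteria, mask, cpp_gamma_search)
}

#' Exhaustive brute-force gamma (verification oracle)
#'
#' Identical contract to [gammaMap()], implemented as an exhaustive sweep of
#' every sample point in the search sphere with no pruning or ordering.
#' Intended for small grids.
#'
#' @inheritParams gammaMap
#' @return a [GammaResult].
#' @export
gammaBruteForce <- function(ref, eval, criteria = gammaCriteria(),
                            mask = NULL) {
  if (is.null(mask)) stop("an analysis mask is required (see analysisMask())")
  .gamma_run(ref, eval, criteria, mask, cpp_gamma_brute)
}

#' Average gamma pass rate
#'
#' Arithmetic mean of pass rates, e.g. over the 10% and 70% threshold rows
#' of one scenario comparison.
#'
#' @param results a list of [GammaResult]s or a numeric vector of pass
#'   rates (percent).
#' @return percent.
#' @export
averagePassRate <- function(results) {
  if (length(results) == 0) stop("no pass rates to average")
  rates <- if (is.numeric(results)) results
           else vapply(results, function(r) r@pass_rate, numeric(1))
  mean(rates)
}
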