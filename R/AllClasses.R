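#' @import methods
NULL

.check_grid <- function(object) {
  msg <- character()
  if (length(object@spacing) != 3 || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (mm/voxel)")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite 3-vector (mm)")
  if (!all(dim(object@orientation) == c(3, 3)) ||
      max(abs(crossprod(object@orientation) - diag(3))) > 1e-6)
    msg <- c(msg, "orientation must be a 3x3 orthonormal matrix")
  if (length(dim(object@values)) != 3)
    msg <- c(msg, "values must be a 3D array")
  msg
}

#' Virtual base class for 3D image grids
#'
#' Carries the geometry shared by all volumetric classes: voxel spacing in mm,
#' the world position (mm) of the centre of voxel (1,1,1), and a 3x3
#' direction-cosine matrix. World coordinates follow the LPS convention
#' throughout the package; after resampling all volumes are axis-aligned
#' (identity orientation).
#'
#' @slot values 3D array of voxel values.
#' @slot spacing numeric(3), mm per voxel along each axis.
#' @slot origin numeric(3), world coordinates (mm) of the first voxel centre.
#' @slot orientation 3x3 orthonormal direction-cosine matrix.
#' @name ImageGrid3D-class
#' @aliases ImageGrid3D
#' @exportClass ImageGrid3D
setClass("ImageGrid3D",
         representation("VIRTUAL", values = "array", spacing = "numeric",
                        origin = "numeric", orientation = "matrix"))

#' CT volume in Hounsfield units
#'
#' The carrier for all image arithmetic: a 3D HU-valued grid with full world
#' geometry. Air is -1000 HU and water 0 HU.
#'
#' @exportClass CTVolume
setClass("CTVolume", contains = "ImageGrid3D",
         validity = function(object) {
           msg <- .check_grid(object)
           if (anyNA(object@values) || any(!is.finite(object@values)))
             msg <- c(msg, "HU values must be finite")
           if (length(msg)) msg else TRUE
         })

#' Binary voxel mask on an image grid
#'
#' @exportClass Mask
setClass("Mask", contains = "ImageGrid3D",
         validity = function(object) {
           msg <- .check_grid(object)
           if (!is.logical(object@values))
             msg <- c(msg, "mask values must be logical")
           if (anyNA(object@values))
             msg <- c(msg, "mask values must not contain NA")
           if (length(msg)) msg else TRUE
         })

#' Physical-density volume (g/cm3)
#'
#' @exportClass DensityVolume
setClass("DensityVolume", contains = "ImageGrid3D",
         validity = function(object) {
           msg <- .check_grid(object)
           if (any(object@values < 0)) msg <- c(msg, "density must be >= 0")
           if (length(msg)) msg else TRUE
         })

#' Relative 3D dose grid
#'
#' Voxel values are percent of the distribution's own maximum (0-100) over
#' the analysis extent; voxels proximal to the applicator bevel are 0.
#'
#' @slot meta list with at least the scenario label.
#' @exportClass DoseGrid
setClass("DoseGrid", contains = "ImageGrid3D",
         representation(meta = "list"),
         prototype(meta = list()),
         validity = function(object) {
           msg <- .check_grid(object)
           if (any(object@values < -1e-9)) msg <- c(msg, "dose must be >= 0")
           if (length(msg)) msg else TRUE
         })

#' Rigid transform between world coordinate frames
#'
#' Maps moving-image world coordinates (mm, LPS) into fixed-image world
#' coordinates: x_fixed = rotation %*% x_moving + translation.
#'
#' @slot rotation 3x3 rotation matrix (det = +1).
#' @slot translation numeric(3), mm.
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"),
         validity = function(object) {
           msg <- character()
           if (!all(dim(object@rotation) == c(3, 3)) ||
               max(abs(crossprod(object@rotation) - diag(3))) > 1e-6)
             msg <- c(msg, "rotation must be 3x3 orthonormal")
           else if (det(object@rotation) < 0)
             msg <- c(msg, "rotation must be proper (det = +1)")
           if (length(object@translation) != 3 ||
               any(!is.finite(object@translation)))
             msg <- c(msg, "translation must be a finite 3-vector (mm)")
           if (length(msg)) msg else TRUE
         })

#' Applicator geometry specification
#'
#' The rigid PMMA tube that collimates the electron beam. `diameter_mm` is the
#' inner (aperture) diameter; the wall adds `wall_mm` outward. The distal end
#' is cut by a plane tilted `bevel_deg` from the plane normal to the axis.
#'
#' @exportClass ApplicatorSpec
setClass("ApplicatorSpec",
         representation(diameter_mm = "numeric", bevel_deg = "numeric",
                        wall_mm = "numeric", length_mm = "numeric",
                        wall_hu = "numeric"),
         validity = function(object) {
           msg <- character()
           if (object@diameter_mm <= 0) msg <- c(msg, "diameter must be > 0")
           if (object@bevel_deg < 0 || object@bevel_deg > 60)
             msg <- c(msg, "bevel angle must lie in [0, 60] degrees")
           if (object@wall_mm <= 0) msg <- c(msg, "wall thickness must be > 0")
           if (object@length_mm <= 0) msg <- c(msg, "tube length must be > 0")
           if (length(msg)) msg else TRUE
         })

#' Applicator pose (6 DOF plus bevel roll)
#'
#' `bevel_centre` is the world position (mm) of the centre of the elliptical
#' exit face; `axis` is a unit vector pointing distally (into tissue);
#' `roll_deg` is the angle of the bevel's shorter edge about the axis,
#' measured in the canonical in-plane basis (see [poseBasis()]).
#'
#' @exportClass ApplicatorPose
setClass("ApplicatorPose",
         representation(bevel_centre = "numeric", axis = "numeric",
                        roll_deg = "numeric", roll_undefined = "logical",
                        fitted_diameter_mm = "numeric"),
         prototype(roll_undefined = FALSE, fitted_diameter_mm = NA_real_),
         validity = function(object) {
           msg <- character()
           if (length(object@axis) != 3 ||
               abs(sqrt(sum(object@axis^2)) - 1) > 1e-6)
             msg <- c(msg, "axis must be a unit 3-vector")
           if (length(object@bevel_centre) != 3 ||
               any(!is.finite(object@bevel_centre)))
             msg <- c(msg, "bevel_centre must be a finite 3-vector (mm)")
           if (!object@roll_undefined &&
               (object@roll_deg < 0 || object@roll_deg >= 360))
             msg <- c(msg, "roll must lie in [0, 360)")
           if (length(msg)) msg else TRUE
         })

#' Electron beam specification
#'
#' @slot energy_mev nominal electron energy (MeV).
#' @slot spec,pose applicator geometry and placement.
#' @slot ssd_mm virtual point-source distance from the bevel centre (mm).
#' @slot prescription_gy prescribed dose (Gy) at the 90% isodose.
#' @exportClass BeamSpec
setClass("BeamSpec",
         representation(energy_mev = "numeric", spec = "ApplicatorSpec",
                        pose = "ApplicatorPose", ssd_mm = "numeric",
                        prescription_gy = "numeric"),
         prototype(ssd_mm = 1000, prescription_gy = NA_real_),
         validity = function(object) {
           msg <- character()
           if (object@energy_mev <= 0) msg <- c(msg, "energy must be > 0")
           if (object@ssd_mm <= 0) msg <- c(msg, "source distance must be > 0")
           if (length(msg)) msg else TRUE
         })

#' Percentage-depth-dose model for the pencil-beam engine
#'
#' Per-energy anchors of the central-axis depth-dose curve in water:
#' surface fraction, R100 (depth of maximum), R90, R50, practical range Rp
#' (all mm water-equivalent) and the bremsstrahlung tail fraction, plus the
#' lateral penumbra parameters sigma0 (mm), k_we and k_geo
#' (mm per mm of water-equivalent / geometric depth).
#'
#' @slot energies named list, one entry per energy in MeV.
#' @slot lateral list with sigma0_mm, k_we, k_geo.
#' @exportClass PDDModel
setClass("PDDModel",
         representation(energies = "list", lateral = "list"),
         validity = function(object) {
           for (nm in names(object@energies)) {
             e <- object@energies[[nm]]
             need <- c("surface", "r100", "r90", "r50", "rp", "tail")
             if (!all(need %in% names(e)))
               return(sprintf("energy %s: missing PDD anchors", nm))
             if (!(0 < e$r100 && e$r100 < e$r90 && e$r90 < e$r50 &&
                   e$r50 < e$rp))
               return(sprintf("energy %s: need 0 < R100 < R90 < R50 < Rp", nm))
           }
           TRUE
         })

#' The five labelled scenario CT volumes
#'
#' All five share one grid: the intraoperative gold standard and the four
#' derived preoperative variants whose doses are gamma-compared against it.
#'
#' @exportClass ScenarioSet
setClass("ScenarioSet",
         representation(intraCT = "CTVolume", preCT_water = "CTVolume",
                        preCT = "CTVolume", preCT_water_air = "CTVolume",
                        preCT_air = "CTVolume", provenance = "list"),
         prototype(provenance = list()))

#' Gamma-analysis criteria
#'
#' Defaults follow the 3%/3 mm, global-normalisation protocol with reference
#' dose thresholds of 10% or 70%.
#'
#' @exportClass GammaCriteria
setClass("GammaCriteria",
         representation(dose_tol_pct = "numeric", dta_mm = "numeric",
                        threshold_pct = "numeric", normalisation = "character",
                        norm_value = "numeric", search_radius_mm = "numeric",
                        step_frac = "numeric"),
         prototype(dose_tol_pct = 3, dta_mm = 3, threshold_pct = 10,
                   normalisation = "global", norm_value = NA_real_,
                   search_radius_mm = 9, step_frac = 1 / 3),
         validity = function(object) {
           msg <- character()
           if (object@dose_tol_pct <= 0 || object@dta_mm <= 0 ||
               object@search_radius_mm <= 0 || object@step_frac <= 0)
             msg <- c(msg, "criteria must all be positive")
           if (object@threshold_pct <= 0 || object@threshold_pct >= 100)
             msg <- c(msg, "threshold must lie in (0, 100)")
           if (!object@normalisation %in% c("global", "local"))
             msg <- c(msg, "normalisation must be 'global' or 'local'")
           if (length(msg)) msg else TRUE
         })

#' Result of a 3D gamma analysis
#'
#' @slot gamma 3D array of gamma values, NaN outside the analysis set.
#' @slot mask the analysis [Mask].
#' @slot pass_rate percent of analysed voxels with gamma <= 1.
#' @exportClass GammaResult
setClass("GammaResult",
         representation(gamma = "array", mask = "Mask", pass_rate = "numeric",
                        analysed = "numeric", passed = "numeric",
                        criteria = "GammaCriteria"),
         validity = function(object) {
           if (object@pass_rate < 0 || object@pass_rate > 100)
             return("pass rate must lie in [0, 100]")
           TRUE
         })

#' Synthetic-phantom configuration
#'
#' Full parameterisation of a paired pre/intraoperative CT phantom: a
#' torso-like ellipsoidal body with bone structures, a post-resection cavity
#' with an irregular floor, a PMMA applicator posed over the cavity with a
#' target maximum air gap, a known rigid inter-acquisition motion, and
#' Gaussian HU noise. Construct with [phantomConfig()].
#'
#' @exportClass PhantomConfig
setClass("PhantomConfig",
         representation(dim = "integer", spacing = "numeric",
                        body_halfaxes = "numeric", body_centre = "numeric",
                        flat_top = "logical", flat_top_z = "numeric",
                        tissue_hu = "numeric", bone_hu = "numeric",
                        n_bones = "integer", bone_radius_mm = "numeric",
                        bone_offset_mm = "numeric", bone_z_mm = "numeric",
                        lowdens_hu = "numeric", lowdens_centre = "numeric",
                        lowdens_radius_mm = "numeric",
                        cavity_centre_xy = "numeric",
                        cavity_radius_mm = "numeric",
                        cavity_depth_mm = "numeric",
                        irregularity_mm = "numeric", n_bumps = "integer",
                        fluid_depth_mm = "numeric", fluid_hu = "numeric",
                        spec = "ApplicatorSpec", tilt_deg = "numeric",
                        roll_deg = "numeric", target_gap_mm = "numeric",
                        motion_rot_deg = "numeric",
                        motion_trans_mm = "numeric",
                        noise_sigma_hu = "numeric", seed = "integer"))

#' A generated phantom case
#'
#' @slot preop,intraop the paired [CTVolume]s.
#' @slot truth list with the ground-truth pose, motion, masks
#'   (air_gap, applicator_wall, bone, bone_pre, body, cavity), the cavity
#'   floor function and the analytic maximum air gap (mm).
#' @exportClass PhantomCase
setClass("PhantomCase",
         representation(preop = "CTVolume", intraop = "CTVolume",
                        truth = "list", config = "PhantomConfig"))

#' Configuration of a full analysis case
#'
#' @exportClass CaseConfig
setClass("CaseConfig",
         representation(preop = "ANY", intraop = "ANY", beam = "BeamSpec",
                        model = "PDDModel", thresholds = "numeric",
                        grid_mm = "numeric", axis_hint = "ANY",
                        bone_seeds = "ANY", constraints = "list",
                        output_dir = "character", seed = "integer",
                        write_intermediates = "logical"),
         prototype(thresholds = c(10, 70), grid_mm = 1.5, axis_hint = NULL,
                   bone_seeds = NULL, constraints = list(),
                   output_dir = NA_character_, seed = 1L,
                   write_intermediates = FALSE))

#' Per-case analysis report
#'
#' Pass-rate table in the classic layout: one row per scenario comparison
#' against the intraoperative gold standard, one column per reference dose
#' threshold, plus the per-comparison average, the RMS HU difference between
#' the registered preoperative and intraoperative image over tissue voxels
#' inside the dose extent, and the maximum air-gap distance.
#'
#' @exportClass CaseReport
setClass("CaseReport",
         representation(pass_rates = "matrix", averages = "numeric",
                        rms_hu = "numeric", max_gap_mm = "numeric",
                        provenance = "list"),
         validity = function(object) {
           msg <- character()
           if (!all(dim(object@pass_rates) == c(4, 2)))
             msg <- c(msg, "pass-rate table must be 4 comparisons x 2 thresholds")
           pr <- object@pass_rates
           if (any(pr < 0 | pr > 100)) msg <- c(msg, "pass rates must lie in [0,100]")
           if (length(object@averages) != 4)
             msg <- c(msg, "need one average per comparison")
           if (length(msg)) msg else TRUE
         })
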