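#' Voxel values of a volumetric object
#' @param x an [ImageGrid3D] derivative.
#' @return the underlying 3D array.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Voxel spacing in mm
#' @param x an [ImageGrid3D] derivative.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' World position (mm) of the first voxel centre
#' @param x an [ImageGrid3D] derivative.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Direction-cosine matrix
#' @param x an [ImageGrid3D] derivative.
#' @export
setGeneric("orientation", function(x) standardGeneric("orientation"))

#' Grid dimensions (voxels)
#' @param x an [ImageGrid3D] derivative.
#' @export
setGeneric("imgDim", function(x) standardGeneric("imgDim"))

#' @rdname voxels
#' @export
setMethod("voxels", "ImageGrid3D", function(x) x@values)
#' @rdname spacing
#' @export
setMethod("spacing", "ImageGrid3D", function(x) x@spacing)
#' @rdname origin
#' @export
setMethod("origin", "ImageGrid3D", function(x) x@origin)
#' @rdname orientation
#' @export
setMethod("orientation", "ImageGrid3D", function(x) x@orientation)
#' @rdname imgDim
#' @export
setMethod("imgDim", "ImageGrid3D", function(x) dim(x@values))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("CTVolume %dx%dx%d, spacing %s mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = "x"),
              min(object@values), max(object@values)))
})

setMethod("show", "Mask", function(object) {
  d <- dim(object@values)
  cat(sprintf("Mask %dx%dx%d, spacing %s mm, %d voxels set\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = "x"),
              sum(object@values)))
})

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@values)
  lab <- if (!is.null(object@meta$scenario)) object@meta$scenario else "?"
  cat(sprintf("DoseGrid [%s] %dx%dx%d, max %.1f%%\n", lab, d[1], d[2], d[3],
              max(object@values)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%s) mm\n", ang,
              paste(format(object@translation, digits = 3), collapse = ", ")))
})

setMethod("show", "ApplicatorPose", function(object) {
  cat(sprintf("ApplicatorPose: bevel centre (%s) mm, axis (%s), roll %s\n",
              paste(format(object@bevel_centre, digits = 4), collapse = ", "),
              paste(format(object@axis, digits = 3), collapse = ", "),
              if (object@roll_undefined) "undefined (bevel 0)"
              else sprintf("%.1f deg", object@roll_deg)))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("GammaResult: %.1f%% of %d voxels pass (%g%%/%g mm, threshold %g%%)\n",
              object@pass_rate, object@analysed, object@criteria@dose_tol_pct,
              object@criteria@dta_mm, object@criteria@threshold_pct))
})

setMethod("show", "CaseReport", function(object) {
  cat("IOERT case report: gamma pass rates (%)\n")
  tab <- cbind(object@pass_rates, average = object@averages)
  print(round(tab, 1))
  cat(sprintf("RMS HU difference (tissue, dose extent): %.1f HU\n", object@rms_hu))
  cat(sprintf("Maximum air-gap distance: %.1f mm\n", object@max_gap_mm))
})
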