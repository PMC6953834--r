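#' @useDynLib ioertdose, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a CTVolume
#'
#' @param values 3D array of HU values.
#' @param spacing numeric(3) mm/voxel.
#' @param origin numeric(3), world position (mm) of the first voxel centre.
#' @param orientation 3x3 direction cosines (identity by default).
#' @return a [CTVolume].
#' @export
CTVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     orientation = diag(3)) {
  storage.mode(values) <- "double"
  new("CTVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' Construct a Mask on the grid of an existing volume
#'
#' @param values 3D logical array.
#' @param like an [ImageGrid3D] supplying the grid, or NULL to pass
#'   spacing/origin/orientation explicitly.
#' @inheritParams CTVolume
#' @export
Mask <- function(values, like = NULL, spacing = c(1, 1, 1),
                 origin = c(0, 0, 0), orientation = diag(3)) {
  if (!is.null(like)) {
    spacing <- like@spacing; origin <- like@origin
    orientation <- like@orientation
    if (!all(dim(values) == dim(like@values)))
      stop("mask shape must match the parent volume exactly")
  }
  storage.mode(values) <- "logical"
  new("Mask", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

.new_like <- function(class, values, like, meta = NULL) {
  if (identical(class, "DoseGrid"))
    new(class, values = values, spacing = like@spacing, origin = like@origin,
        orientation = like@orientation, meta = if (is.null(meta)) list() else meta)
  else
    new(class, values = values, spacing = like@spacing, origin = like@origin,
        orientation = like@orientation)
}

.stopifnot_same_grid <- function(...) {
  vols <- list(...)
  a <- vols[[1]]
  for (b in vols[-1]) {
    if (!all(dim(a@values) == dim(b@values)) ||
        max(abs(a@spacing - b@spacing)) > 1e-6 ||
        max(abs(a@origin - b@origin)) > 1e-4 ||
        max(abs(a@orientation - b@orientation)) > 1e-6)
      stop("volumes must share one grid (dimensions, spacing, origin, orientation)")
  }
  invisible(TRUE)
}

# 0-based voxel index matrix for every voxel, column-major order
.grid_index0 <- function(d) {
  cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

#' World coordinates of every voxel centre
#'
#' @param vol an [ImageGrid3D] derivative.
#' @return an N x 3 matrix (mm), rows in column-major voxel order.
#' @export
voxelCentres <- function(vol) {
  idx <- .grid_index0(dim(vol@values))
  sc <- idx * rep(vol@spacing, each = nrow(idx))
  if (max(abs(vol@orientation - diag(3))) > 1e-12)
    sc <- sc %*% t(vol@orientation)
  sweep(sc, 2, vol@origin, "+")
}

# world (N x 3) -> continuous 0-based voxel index
.world_to_index0 <- function(vol, w) {
  w <- sweep(w, 2, vol@origin, "-")
  if (max(abs(vol@orientation - diag(3))) > 1e-12)
    w <- w %*% vol@orientation  # t(R) applied from the right
  sweep(w, 2, vol@spacing, "/")
}

#' Read a CT volume from disk
#'
#' Accepts NIfTI-1 (.nii / .nii.gz) and uncompressed MetaImage (.mha).
#' Spacing and the world position of the first voxel centre are taken from
#' the stored affine; values are returned as stored.
#'
#' @param path file path.
#' @return a [CTVolume].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (grepl("\\.mha$", path, ignore.case = TRUE)) return(.read_mha(path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           conditionMessage(e)))
  if (length(dim(img)) != 3)
    stop("expected a 3D image, got ", length(dim(img)), " dimensions")
  arr <- array(as.double(img), dim(img))
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(sp <= 0)) sp <- RNifti::pixdim(img)
  ori <- sweep(aff[1:3, 1:3], 2, sp, "/")
  CTVolume(arr, spacing = sp, origin = aff[1:3, 4], orientation = ori)
}

#' Write a volume or mask to NIfTI
#'
#' Values round-trip losslessly through [readVolume()] at the configured
#' datatype; masks are written as 8-bit.
#'
#' @param vol a [CTVolume], [DoseGrid], [DensityVolume] or [Mask].
#' @param path output path (.nii or .nii.gz).
#' @param datatype one of "double", "float", "int16", "uint8"; masks default
#'   to "uint8", everything else to "double".
#' @export
writeVolume <- function(vol, path, datatype = NULL) {
  if (!dir.exists(dirname(path)))
    stop("cannot write '", path, "': parent directory does not exist")
  if (is.null(datatype)) datatype <- if (is(vol, "Mask")) "uint8" else "double"
  arr <- vol@values
  if (is.logical(arr)) { arr <- array(as.integer(arr), dim(arr)) }
  img <- RNifti::asNifti(arr,
                         reference = list(pixdim = c(1, vol@spacing, 0, 0, 0, 0)))
  aff <- rbind(cbind(sweep(vol@orientation, 2, vol@spacing, "*"), vol@origin),
               c(0, 0, 0, 1))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  ok <- tryCatch({ RNifti::writeNifti(img, path, datatype = datatype); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("failed to write '", path, "'")
  invisible(path)
}

#' Read a mask written by [writeVolume()]
#'
#' @param path file path.
#' @param like optional volume whose grid the mask must match.
#' @export
readMask <- function(path, like = NULL) {
  v <- readVolume(path)
  m <- Mask(v@values != 0, spacing = v@spacing, origin = v@origin,
            orientation = v@orientation)
  if (!is.null(like)) .stopifnot_same_grid(m, like)
  m
}

# Minimal MetaImage reader: uncompressed local-data 3D images.
.read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!is.null(hdr$ObjectType) && hdr$ObjectType != "Image")
    stop("MetaImage object type must be Image")
  nd <- as.integer(hdr$NDims)
  if (!identical(nd, 3L)) stop("expected a 3D image, got ", nd, " dimensions")
  if (!is.null(hdr$CompressedData) && toupper(hdr$CompressedData) == "TRUE")
    stop("compressed MetaImage data is not supported")
  if (hdr$ElementDataFile != "LOCAL")
    stop("only LOCAL MetaImage data is supported")
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  ori <- if (!is.null(hdr$TransformMatrix))
    matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3,
           byrow = TRUE) else diag(3)
  type <- hdr$ElementType
  n <- prod(d)
  raw_vals <- switch(type,
    MET_SHORT  = readBin(con, "integer", n, size = 2, signed = TRUE,
                         endian = "little"),
    MET_USHORT = readBin(con, "integer", n, size = 2, signed = FALSE,
                         endian = "little"),
    MET_UCHAR  = as.integer(readBin(con, "raw", n)),
    MET_FLOAT  = readBin(con, "double", n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "double", n, size = 8, endian = "little"),
    stop("unsupported MetaImage element type: ", type))
  if (length(raw_vals) < n) stop("truncated MetaImage data")
  CTVolume(array(as.double(raw_vals), d), spacing = sp, origin = org,
           orientation = ori)
}

#' Resample a volume to isotropic spacing
#'
#' The output grid keeps the world position of the first voxel centre, is
#' axis-aligned (any input orientation is folded into the resample) and
#' covers the input's physical extent to within one voxel. HU and dose use
#' trilinear interpolation; masks use nearest-neighbour.
#'
#' @param vol a [CTVolume], [DoseGrid], [DensityVolume] or [Mask].
#' @param spacing_mm target isotropic spacing (default 1.5 mm).
#' @param interpolation "trilinear" or "nearest"; the default picks by class.
#' @param outside fill value for points outside the input extent
#'   (default -1000 for HU, 0 otherwise).
#' @return an object of the same class on the new grid.
#' @export
resampleIsotropic <- function(vol, spacing_mm = 1.5,
                              interpolation = NULL, outside = NULL) {
  stopifnot(spacing_mm > 0)
  is_mask <- is(vol, "Mask")
  if (is.null(interpolation))
    interpolation <- if (is_mask) "nearest" else "trilinear"
  interpolation <- match.arg(interpolation, c("trilinear", "nearest"))
  if (is.null(outside)) outside <- if (is(vol, "CTVolume")) -1000 else 0
  d_in <- dim(vol@values)
  n_out <- pmax(1L, as.integer(ceiling(d_in * vol@spacing / spacing_mm)))
  out_grid <- CTVolume(array(0, n_out), spacing = rep(spacing_mm, 3),
                       origin = vol@origin)
  w <- voxelCentres(out_grid)
  idx <- .world_to_index0(vol, w)
  # the output grid covers the input extent to within one voxel: clamp the
  # boundary overhang onto the edge voxels instead of treating it as outside
  idx <- pmin(pmax(idx, 0), rep(d_in - 1L, each = nrow(idx)))
  src <- vol@values
  if (is.logical(src)) storage.mode(src) <- "double"
  vals <- if (interpolation == "trilinear")
    cpp_sample_trilinear(src, d_in, idx, outside)
  else
    cpp_sample_nearest(src, d_in, idx, outside)
  arr <- array(vals, n_out)
  if (is_mask)
    Mask(arr != 0, spacing = rep(spacing_mm, 3), origin = vol@origin)
  else
    .new_like(class(vol), arr, out_grid,
              meta = if (is(vol, "DoseGrid")) vol@meta else NULL)
}

#' Load the HU-to-density calibration table
#'
#' The shipped table is a piecewise-linear stand-in with knots at
#' (-1000, 0.00121), (0, 1.0), (1000, 1.59) g/cm3; edit the YAML to match a
#' scanner-specific calibration.
#'
#' @param path YAML file with a `knots:` list of `[HU, density]` pairs;
#'   NULL loads the packaged default.
#' @return a two-column matrix (hu, density), ordered by HU.
#' @export
loadHuDensityTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hu_density.yaml", package = "ioertdose")
  cfg <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(cfg$knots, unlist))
  colnames(tab) <- c("hu", "density")
  tab <- tab[order(tab[, 1]), , drop = FALSE]
  if (any(diff(tab[, 2]) < 0))
    stop("HU-to-density table must be monotone non-decreasing")
  tab
}

#' Convert HU to physical density (g/cm3)
#'
#' Piecewise-linear interpolation between the calibration knots, clamped at
#' the table ends; monotone non-decreasing by construction.
#'
#' @param hu a numeric vector/array of HU, or a [CTVolume].
#' @param table calibration matrix from [loadHuDensityTable()].
#' @return numeric of the same shape, or a [DensityVolume] for CTVolume input.
#' @export
huToDensity <- function(hu, table = loadHuDensityTable()) {
  if (is(hu, "CTVolume")) {
    dens <- huToDensity(hu@values, table)
    return(.new_like("DensityVolume", array(dens, dim(hu@values)), hu))
  }
  stats::approx(table[, 1], table[, 2], xout = as.numeric(hu), rule = 2,
                ties = "ordered")$y
}

#' Root-mean-square HU difference over a mask
#'
#' @param a,b [CTVolume]s on one grid.
#' @param mask a [Mask] on the same grid.
#' @return scalar HU.
#' @export
rmsHuDifference <- function(a, b, mask) {
  .stopifnot_same_grid(a, b, mask)
  sel <- mask@values
  if (!any(sel)) stop("empty mask: RMS difference is undefined")
  sqrt(mean((a@values[sel] - b@values[sel])^2))
}
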