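#' Configure a full analysis case
#'
#' @param preop,intraop [CTVolume]s or file paths readable by
#'   [readVolume()].
#' @param beam a [BeamSpec] (its pose slot is ignored: the pose is estimated
#'   from the intraoperative image).
#' @param model a [PDDModel]; default the shipped model.
#' @param thresholds reference-dose thresholds (%) for the gamma table.
#' @param grid_mm analysis grid spacing (default 1.5 mm).
#' @param axis_hint optional list(point =, direction =) seeding the wall
#'   segmentation; default a vertical axis through the grid centre.
#' @param bone_seeds optional N x 3 matrix of 1-based voxel indices on the
#'   resampled intraoperative grid; default automatic high-HU seeds.
#' @param constraints optional named list of [Mask]s (elements `bone`,
#'   `gap`, `wall`), the reproducible stand-in for manual delineation.
#' @param output_dir optional directory; when set, intermediates and the
#'   report are written there.
#' @param seed seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return a [CaseConfig].
#' @export
caseConfig <- function(preop, intraop, beam, model = loadPddModel(),
                       thresholds = c(10, 70), grid_mm = 1.5,
                       axis_hint = NULL, bone_seeds = NULL,
                       constraints = list(), output_dir = NA_character_,
                       seed = 1L) {
  new("CaseConfig", preop = preop, intraop = intraop, beam = beam,
      model = model, thresholds = thresholds, grid_mm = grid_mm,
      axis_hint = axis_hint, bone_seeds = bone_seeds,
      constraints = constraints, output_dir = output_dir,
      seed = as.integer(seed),
      write_intermediates = !is.na(output_dir))
}

.load_vol <- function(x) if (is.character(x)) readVolume(x) else x

.stage <- function(tag, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE))
}

#' Run the full dose-comparison analysis for one case
#'
#' Orchestrates the whole method: resample both CTs to the analysis grid,
#' segment bone, rigidly register the preoperative to the intraoperative
#' image (NMI over bone), segment the applicator wall and estimate the
#' pose, segment the air gap, build the five scenarios, compute dose on
#' each, and gamma-compare the four preoperative variants against the
#' intraoperative gold standard at each threshold. Deterministic.
#'
#' @param cfg a [CaseConfig].
#' @param dose_engine a function with the contract of [computeDose()]; the
#'   documented extension point for plugging in a Monte Carlo engine.
#' @return a [CaseReport]; the full stage outputs are attached as
#'   attribute "artifacts" (scenarios, doses, masks, transform, pose).
#' @export
runCase <- function(cfg, dose_engine = computeDose) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function(tag) {
    tt <- proc.time()[["elapsed"]]
    timings[[tag]] <<- tt - t0
    t0 <<- tt
  }
  intra0 <- .load_vol(cfg@intraop)
  pre0 <- .load_vol(cfg@preop)
  intra <- .stage("resample", resampleIsotropic(intra0, cfg@grid_mm))
  pre <- .stage("resample", resampleIsotropic(pre0, cfg@grid_mm))
  tic("resample")

  seeds <- if (is.null(cfg@bone_seeds)) autoBoneSeeds(intra) else cfg@bone_seeds
  bone <- .stage("segment_bone",
                 segmentBone(intra, seeds, constraint = cfg@constraints$bone))
  tic("segment_bone")

  reg <- .stage("register", rigidRegister(intra, pre, bone))
  pre_reg <- applyTransform(pre, reg, reference = intra)
  tic("register")

  hint <- cfg@axis_hint
  if (is.null(hint)) {
    ctr <- intra@origin + (dim(intra@values) - 1) * intra@spacing / 2
    hint <- list(point = ctr, direction = c(0, 0, -1))
  }
  wall <- .stage("segment_wall",
                 segmentApplicatorWall(intra, hint, cfg@beam@spec))
  pose <- .stage("pose", estimatePose(wall, cfg@beam@spec, vol = intra,
                                      init_axis = hint$direction))
  tic("pose")

  gap <- .stage("segment_gap",
                segmentAirGap(intra, pose, cfg@beam@spec,
                              constraint = cfg@constraints$gap))
  body_intra <- .stage("body_mask", bodyMask(intra, wall = wall))
  body_pre <- .stage("body_mask", bodyMask(pre_reg))
  tic("segment")

  scen <- .stage("scenarios",
                 buildScenarios(intra, pre_reg, gap, pose, cfg@beam@spec,
                                body_pre))
  beam <- cfg@beam
  beam@pose <- pose
  labels <- c("intraCT", scenarioComparisons())
  doses <- lapply(labels, function(lb) {
    dg <- .stage("dose", dose_engine(scenario(scen, lb), beam, cfg@model))
    dg@meta$scenario <- lb
    dg
  })
  names(doses) <- labels
  tic("dose")

  ref <- doses$intraCT
  # analysis volume of interest: bounding box of the nonzero reference dose
  nz <- which(ref@values > 0, arr.ind = TRUE)
  bbox <- array(FALSE, dim(ref@values))
  bbox[min(nz[, 1]):max(nz[, 1]), min(nz[, 2]):max(nz[, 2]),
       min(nz[, 3]):max(nz[, 3])] <- TRUE
  pr <- matrix(NA_real_, 4, 2,
               dimnames = list(scenarioComparisons(),
                               paste0("dose>", cfg@thresholds, "%")))
  gammas <- list()
  for (comp in scenarioComparisons()) {
    for (ti in seq_along(cfg@thresholds)) {
      crit <- gammaCriteria(threshold_pct = cfg@thresholds[ti])
      am <- .stage("gamma", analysisMask(ref, body_intra, crit))
      gr <- .stage("gamma", gammaMap(ref, doses[[comp]], crit, am))
      pr[comp, ti] <- gr@pass_rate
      gammas[[paste(comp, cfg@thresholds[ti], sep = "_")]] <- gr
    }
  }
  tic("gamma")

  tissue_voi <- Mask(body_intra@values & bbox, like = body_intra)
  rms <- rmsHuDifference(intra, pre_reg, tissue_voi)
  max_gap <- maxAirGapDistance(gap, pose, cfg@beam@spec)

  report <- new("CaseReport", pass_rates = pr, averages = rowMeans(pr),
                rms_hu = rms, max_gap_mm = max_gap,
                provenance = list(
                  seed = cfg@seed, grid_mm = cfg@grid_mm,
                  thresholds = cfg@thresholds,
                  energy_mev = cfg@beam@energy_mev,
                  registration_nmi = attr(reg, "nmi"),
                  fitted_diameter_mm = pose@fitted_diameter_mm,
                  gap_voxels = sum(gap@values),
                  timings_s = as.list(timings),
                  package_version = as.character(utils::packageVersion("ioertdose"))))
  artifacts <- list(scenarios = scen, doses = doses, transform = reg,
                    pose = pose, bone = bone, wall = wall, gap = gap,
                    body_intra = body_intra, body_pre = body_pre,
                    gammas = gammas, pre_registered = pre_reg)
  if (isTRUE(cfg@write_intermediates) && !is.na(cfg@output_dir)) {
    dir.create(cfg@output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg@output_dir
    for (lb in labels) {
      writeVolume(scenario(scen, lb), file.path(od, paste0(lb, ".nii.gz")),
                  datatype = "float")
      writeVolume(doses[[lb]], file.path(od, paste0("dose_", lb, ".nii.gz")),
                  datatype = "float")
    }
    writeVolume(gap, file.path(od, "air_gap.nii.gz"))
    writeVolume(bone, file.path(od, "bone.nii.gz"))
    writeVolume(body_intra, file.path(od, "body.nii.gz"))
    writeTransform(reg, file.path(od, "transform.json"))
    writePose(pose, file.path(od, "pose.json"))
    writeReport(report, file.path(od, "report"))
  }
  attr(report, "artifacts") <- artifacts
  report
}

#' Write an applicator pose as JSON
#' @param pose an [ApplicatorPose].
#' @param path output path.
#' @export
writePose <- function(pose, path) {
  jsonlite::write_json(list(bevel_centre_mm = pose@bevel_centre,
                            axis = pose@axis, roll_deg = pose@roll_deg,
                            roll_undefined = pose@roll_undefined,
                            fitted_diameter_mm = pose@fitted_diameter_mm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a case report as CSV and JSON
#'
#' The CSV follows the classic table layout (rows = scenario comparisons,
#' columns = the two dose thresholds plus the per-comparison average); the
#' JSON carries the full report including provenance.
#'
#' @param report a [CaseReport].
#' @param path base path; ".csv" and ".json" are appended.
#' @return the two paths, invisibly.
#' @export
writeReport <- function(report, path) {
  tab <- data.frame(comparison = rownames(report@pass_rates),
                    report@pass_rates, average = report@averages,
                    check.names = FALSE)
  csv <- paste0(path, ".csv"); js <- paste0(path, ".json")
  utils::write.csv(tab, csv, row.names = FALSE)
  jsonlite::write_json(list(pass_rates = as.data.frame(tab),
                            rms_hu = report@rms_hu,
                            max_gap_mm = report@max_gap_mm,
                            provenance = report@provenance),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Read a case report written by [writeReport()]
#' @param path base path without extension (as given to [writeReport()]).
#' @return a [CaseReport] (without provenance-only attributes it never had).
#' @export
readReport <- function(path) {
  x <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  need <- c("pass_rates", "rms_hu", "max_gap_mm")
  if (!all(need %in% names(x)))
    stop("report JSON is missing required fields: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  tab <- x$pass_rates
  pr <- as.matrix(tab[, grep("^dose>", names(tab)), drop = FALSE])
  rownames(pr) <- tab$comparison
  new("CaseReport", pass_rates = pr, averages = tab$average,
      rms_hu = x$rms_hu, max_gap_mm = x$max_gap_mm,
      provenance = as.list(x$provenance))
}
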