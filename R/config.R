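## Fixtures, run configuration, serialization and the end-to-end pipeline.

.extdata <- function(f) system.file("extdata", f, package = "dceDRO",
                                    mustWork = TRUE)

#' Load a protocol from YAML
#'
#' @param path YAML file with keys tr_s, te_s, flip_deg, fov_mm,
#'   acquired_matrix, temporal_resolution_s, n_pre, n_post, r1_per_mM_s,
#'   r2star_per_mM_s, snr_nawm. Defaults to the shipped reference protocol.
#' @return An \linkS4class{MRProtocol}.
#' @export
readProtocol <- function(path = .extdata("protocol_reference.yaml")) {
  y <- yaml::read_yaml(path)
  MRProtocol(tr = y$tr_s, te = y$te_s, flipDeg = y$flip_deg,
             fovMM = unlist(y$fov_mm), acqMatrix = unlist(y$acquired_matrix),
             dtS = y$temporal_resolution_s, nPre = y$n_pre, nPost = y$n_post,
             r1 = y$r1_per_mM_s %||% 3.9, r2star = y$r2star_per_mM_s %||% 4.5,
             snrNAWM = y$snr_nawm %||% 91.5)
}

#' Write a protocol to YAML
#' @param proto an \linkS4class{MRProtocol}.
#' @param path output YAML file.
#' @export
writeProtocol <- function(proto, path) {
  yaml::write_yaml(list(
    tr_s = proto@tr, te_s = proto@te, flip_deg = proto@flipDeg,
    fov_mm = proto@fovMM, acquired_matrix = proto@acqMatrix,
    temporal_resolution_s = proto@dtS, n_pre = proto@nPre,
    n_post = proto@nPost, r1_per_mM_s = proto@r1,
    r2star_per_mM_s = proto@r2star, snr_nawm = proto@snrNAWM), path)
  invisible(path)
}

#' Reference acquisition protocol and tissue parameters
#'
#' Returns the shipped defaults: the reference MR protocol (TR 8.24 ms,
#' TE 3.1 ms, flip 12 degrees, FOV 24 x 24 x 18.4 cm at
#' 0.9375 x 1.25 x 4 mm, 73 s temporal resolution, 1 pre- + 20
#' post-contrast frames) and the ground-truth tissue parameter table.
#'
#' @return list with elements \code{protocol} and \code{table}.
#' @export
loadFixtures <- function() {
  list(protocol = readProtocol(),
       table = readTissueTable(.extdata("tissue_parameters.csv")))
}

#' Desk-scale demo protocol
#'
#' The reference protocol's timing, contrast and relaxivity settings on a
#' proportionally scaled geometry matching the demo phantom: by default a
#' 96 mm isotropic FOV acquired at 48 x 40 x 16 (2 x 2.4 x 6 mm), keeping
#' the reference-protocol property that the slice voxel dimension is by far the
#' coarsest.
#'
#' @param fovMM demo field of view, mm.
#' @param acqMatrix demo acquired matrix.
#' @return An \linkS4class{MRProtocol}.
#' @export
demoProtocol <- function(fovMM = c(96, 96, 96), acqMatrix = c(48L, 40L, 16L)) {
  ref <- readProtocol()
  MRProtocol(tr = ref@tr, te = ref@te, flipDeg = ref@flipDeg,
             fovMM = fovMM, acqMatrix = acqMatrix, dtS = ref@dtS,
             nPre = ref@nPre, nPost = ref@nPost, r1 = ref@r1,
             r2star = ref@r2star, snrNAWM = ref@snrNAWM)
}

#' Default tissue parameter table
#' @return the shipped \code{\link{tissueParameterTable}}.
#' @export
defaultTissueTable <- function() {
  readTissueTable(.extdata("tissue_parameters.csv"))
}

## ---------------------------------------------------------------------------
## Serialization of trajectories and dynamic volumes
## ---------------------------------------------------------------------------

#' Write a motion trajectory to CSV
#' @param trajectory a \linkS4class{MotionTrajectory}.
#' @param path output CSV.
#' @export
writeTrajectory <- function(trajectory, path) {
  tr <- trajectory@transforms
  df <- data.frame(
    frame = seq_along(tr),
    rx_deg = vapply(tr, function(t) t@rotDeg[1], numeric(1)),
    ry_deg = vapply(tr, function(t) t@rotDeg[2], numeric(1)),
    rz_deg = vapply(tr, function(t) t@rotDeg[3], numeric(1)),
    tx_mm = vapply(tr, function(t) t@transMM[1], numeric(1)),
    ty_mm = vapply(tr, function(t) t@transMM[2], numeric(1)),
    tz_mm = vapply(tr, function(t) t@transMM[3], numeric(1)))
  attr <- tr[[1]]@centre
  utils::write.csv(df, path, row.names = FALSE)
  cat(sprintf("# centre_mm,%g,%g,%g\n", attr[1], attr[2], attr[3]),
      file = path, append = TRUE)
  invisible(path)
}

#' Read a motion trajectory from CSV
#' @param path CSV written by \code{\link{writeTrajectory}}.
#' @param severity severity label to attach.
#' @export
readTrajectory <- function(path, severity = "moderate") {
  lines <- readLines(path)
  centre <- c(0, 0, 0)
  cl <- grep("^# centre_mm", lines, value = TRUE)
  if (length(cl)) centre <- as.numeric(strsplit(cl[1], ",")[[1]][2:4])
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  tr <- lapply(seq_len(nrow(df)), function(i)
    RigidTransform(rotDeg = as.numeric(df[i, c("rx_deg", "ry_deg", "rz_deg")]),
                   transMM = as.numeric(df[i, c("tx_mm", "ty_mm", "tz_mm")]),
                   centre = centre))
  new("MotionTrajectory", transforms = tr, severity = severity)
}

#' Write a 4D dynamic series as NIfTI plus a JSON timing sidecar
#' @param series a \linkS4class{DynamicVolume}.
#' @param path output NIfTI path (.nii or .nii.gz); the sidecar replaces
#'   the extension with .json.
#' @export
writeDynamicVolume <- function(series, path) {
  img <- RNifti::asNifti(series@data)
  img <- RNifti::`sform<-`(img, structure(series@affine, code = 2L))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(frame_times_s = series@frameTimes,
                            spacing_mm = series@spacing),
                       side, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a 4D dynamic series written by \code{\link{writeDynamicVolume}}
#' @param path NIfTI path with accompanying .json sidecar.
#' @export
readDynamicVolume <- function(path) {
  img <- RNifti::readNifti(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  DynamicVolume(array(as.numeric(img), dim(img)), spacing = meta$spacing_mm,
                frameTimes = meta$frame_times_s,
                affine = unclass(RNifti::xform(img)))
}

#' Write a parameter map as NIfTI volumes plus a JSON sidecar
#'
#' PS is written in units of 1e-4 per minute and vP in units of 1e-2
#' (percent), the conventional reporting scale for subtle leakage.
#'
#' @param map a \linkS4class{ParameterMap}.
#' @param prefix output path prefix; writes
#'   \code{<prefix>_PS.nii.gz}, \code{<prefix>_vP.nii.gz} and
#'   \code{<prefix>_fit.json}.
#' @export
writeParameterMap <- function(map, prefix) {
  wr <- function(arr, suffix) {
    img <- RNifti::asNifti(arr)
    img <- RNifti::`sform<-`(img, structure(map@affine, code = 2L))
    RNifti::writeNifti(img, paste0(prefix, suffix))
  }
  wr(map@ps * 1e4, "_PS.nii.gz")
  wr(map@vp * 1e2, "_vP.nii.gz")
  jsonlite::write_json(list(ps_units = "1e-4 per minute",
                            vp_units = "1e-2 (percent)",
                            frames_used = map@framesUsed),
                       paste0(prefix, "_fit.json"), auto_unbox = FALSE)
  invisible(prefix)
}

## ---------------------------------------------------------------------------
## Run configuration
## ---------------------------------------------------------------------------

#' Default demo run configuration
#'
#' A desk-scale configuration: 96 mm FOV phantom at 1 mm, demo acquired
#' matrix, moderate motion, all artefact flags on, oracle realignment and
#' segmentation, the median-parameter estimator with and without erosion.
#'
#' @param seed master seed.
#' @param nRuns Monte-Carlo runs (1 = single pass).
#' @return a named list (class \code{"RunConfig"}).
#' @export
defaultRunConfig <- function(seed = 1L, nRuns = 1L) {
  structure(list(
    phantom = list(dim = c(96L, 96L, 96L), spacing_mm = c(1, 1, 1),
                   classes = 1:16, seed = 1L),
    protocol = "demo",
    aif = list(dose_mmol_kg = 0.1, onset_s = 73),
    hct = 0.45,
    severity = "moderate",
    flags = list(startPosition = TRUE, grossMotion = TRUE,
                 motionArtefacts = TRUE, noise = TRUE),
    extracerebral_enhancement = TRUE,
    realign = list(mode = "oracle", interpolation = "linear"),
    segmentation = "oracle",
    estimators = c("median_parameter", "mean_parameter"),
    erode_radii = c(0, 1),
    lowpass_cutoff = NULL,
    exclude_post = 3L,
    n_runs = as.integer(nRuns),
    seed = as.integer(seed)), class = "RunConfig")
}

#' Validate a run configuration
#'
#' Rejects physically impossible or inconsistent settings (unknown
#' severity, estimators, modes; non-positive run counts; a protocol whose
#' TE >= TR or flip >= 90 degrees is rejected by the
#' \linkS4class{MRProtocol} validity itself).
#'
#' @param cfg a run configuration list.
#' @return the validated config, invisibly.
#' @export
validateRunConfig <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!cfg$severity %in% c("none", "low", "moderate", "high"))
    stop("unknown severity: ", cfg$severity)
  bad <- setdiff(cfg$estimators, c("mean_parameter", "median_parameter",
                                   "mean_signal", "median_signal"))
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  if (!cfg$realign$mode %in% c("oracle", "registration", "none"))
    stop("unknown realign mode")
  if (!cfg$segmentation %in% c("oracle", "registration"))
    stop("unknown segmentation mode")
  if (cfg$n_runs < 1) stop("n_runs must be >= 1")
  if (!is.null(cfg$lowpass_cutoff) &&
      (cfg$lowpass_cutoff <= 0 || cfg$lowpass_cutoff > 1))
    stop("lowpass_cutoff must lie in (0, 1]")
  if (cfg$hct <= 0 || cfg$hct >= 1) stop("hct must lie in (0, 1)")
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @rdname runConfigIO
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$phantom$dim <- as.integer(unlist(cfg$phantom$dim))
  cfg$phantom$spacing_mm <- as.numeric(unlist(cfg$phantom$spacing_mm))
  cfg$phantom$classes <- as.integer(unlist(cfg$phantom$classes))
  cfg$estimators <- unlist(cfg$estimators)
  cfg$erode_radii <- as.numeric(unlist(cfg$erode_radii))
  cfg$n_runs <- as.integer(cfg$n_runs)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "RunConfig"
  validateRunConfig(cfg)
  cfg
}

#' @param cfg a run configuration list.
#' @rdname runConfigIO
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

## instantiate the objects a config describes
.configObjects <- function(cfg) {
  validateRunConfig(cfg)
  spec <- phantomSpec(dim = cfg$phantom$dim, spacingMM = cfg$phantom$spacing_mm,
                      classes = cfg$phantom$classes)
  vol <- buildSyntheticHead(spec, seed = cfg$phantom$seed %||% 1L)
  proto <- if (identical(cfg$protocol, "demo")) {
    demoProtocol(fovMM = cfg$phantom$dim * cfg$phantom$spacing_mm)
  } else if (identical(cfg$protocol, "reference")) readProtocol()
  else readProtocol(cfg$protocol)
  aif <- defaultAIF(dose = cfg$aif$dose_mmol_kg %||% 0.1,
                    onsetS = cfg$aif$onset_s %||% proto@dtS)
  list(vol = vol, proto = proto, aif = aif, table = defaultTissueTable())
}

#' Run the full simulate-analyse-summarise pipeline
#'
#' Phantom construction, DRO synthesis, acquisition simulation, optional
#' k-space low-pass filtering, realignment, segmentation propagation, T10
#' map construction, voxelwise Patlak fitting and ROI summaries, with all
#' intermediates optionally persisted to \code{outDir}. With
#' \code{n_runs > 1} the Monte-Carlo harness is run and aggregated instead
#' of a single pass.
#'
#' @param cfg a run configuration (see \code{\link{defaultRunConfig}}).
#' @param outDir output directory (created if needed).
#' @param persistVolumes write NIfTI intermediates (acquired series and
#'   parameter maps) in addition to the CSV/JSON outputs.
#' @return invisibly, a list with the summary data.frame and output paths.
#' @export
runPipeline <- function(cfg = defaultRunConfig(), outDir = tempfile("dro_run_"),
                        persistVolumes = TRUE) {
  obj <- .configObjects(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = cfg$seed, n_runs = cfg$n_runs, severity = cfg$severity,
              flags = cfg$flags, realign = cfg$realign,
              segmentation = cfg$segmentation)
  if (cfg$n_runs > 1L) {
    mc <- runMonteCarlo(obj$vol, obj$table, obj$aif, obj$proto,
                        nRuns = cfg$n_runs, seed = cfg$seed,
                        severity = cfg$severity, flags = cfg$flags,
                        realign = cfg$realign$mode,
                        realignInterp = cfg$realign$interpolation,
                        segmentation = cfg$segmentation,
                        estimators = cfg$estimators,
                        erodeRadii = cfg$erode_radii,
                        lowpassCutoff = cfg$lowpass_cutoff,
                        excludePost = cfg$exclude_post, hct = cfg$hct)
    utils::write.csv(mc, file.path(outDir, "montecarlo.csv"), row.names = FALSE)
    agg <- aggregateMonteCarlo(mc)
    utils::write.csv(agg, file.path(outDir, "roi_summary.csv"),
                     row.names = FALSE)
    log$failed_runs <- attr(mc, "failedRuns")
    summary <- agg
  } else {
    seeds <- childSeeds(cfg$seed, 1L)
    acq <- simulateAcquisition(obj$vol, obj$table, obj$aif, obj$proto,
                               severity = cfg$severity, flags = cfg$flags,
                               seed = seeds[1],
                               extracerebralOn = isTRUE(cfg$extracerebral_enhancement))
    if (!is.null(cfg$lowpass_cutoff))
      acq <- lowpassFilterKspace(acq, cutoff = cfg$lowpass_cutoff)
    ana <- if (cfg$realign$mode == "none") acq
           else realignFrames(acq, mode = cfg$realign$mode,
                              interpolation = cfg$realign$interpolation)
    seg <- propagateSegmentation(obj$vol, acq, table = obj$table,
                                 aif = obj$aif, proto = obj$proto,
                                 mode = cfg$segmentation)
    T10 <- buildT10Map(seg, obj$table)
    pmap <- fitParameterMaps(ana, T10, obj$aif, obj$proto,
                             excludePost = cfg$exclude_post)
    summary <- do.call(rbind, lapply(cfg$estimators, function(est)
      do.call(rbind, lapply(cfg$erode_radii, function(er)
        summarizeROI(map = pmap, series = ana, labelMap = seg,
                     estimator = est, table = obj$table, aif = obj$aif,
                     proto = obj$proto, erodeRadius = er,
                     excludePost = cfg$exclude_post, hct = cfg$hct)))))
    utils::write.csv(summary, file.path(outDir, "roi_summary.csv"),
                     row.names = FALSE)
    if (persistVolumes) {
      writeDynamicVolume(acq, file.path(outDir, "acquired.nii.gz"))
      writeParameterMap(pmap, file.path(outDir, "map"))
    }
    log$sigma <- acq@meta$sigma
  }
  jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(summary = summary, outDir = outDir))
}
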