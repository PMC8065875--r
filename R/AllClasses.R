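#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib dceDRO, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## LabelVolume: integer-labelled 3D grid with voxel spacing and affine
## ---------------------------------------------------------------------------

#' LabelVolume: an integer-labelled 3D head volume
#'
#' Holds the high-resolution ground-truth segmentation: a 3D array of
#' integer class IDs (0 = background), the voxel spacing in mm, the
#' voxel-to-world affine and the ID-to-name table for the tissue classes.
#'
#' @slot labels 3D integer array of class IDs; 0 is background.
#' @slot spacing numeric(3), mm per axis, strictly positive.
#' @slot affine 4x4 voxel(0-based)-to-world matrix, RAS.
#' @slot classNames named character vector; names are class IDs as strings.
#'
#' @aliases LabelVolume-class
#' @exportClass LabelVolume
setClass("LabelVolume",
  representation(labels = "array", spacing = "numeric", affine = "matrix",
                 classNames = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 strictly positive values")
    if (!all(dim(object@affine) == c(4L, 4L))) msg <- c(msg, "affine must be 4x4")
    ids <- sort(unique(as.vector(object@labels)))
    ids <- ids[ids != 0]
    unknown <- setdiff(as.character(ids), names(object@classNames))
    if (length(unknown))
      msg <- c(msg, paste0("label IDs missing from classNames: ",
                           paste(unknown, collapse = ", ")))
    if (any(as.vector(object@labels) < 0)) msg <- c(msg, "negative label IDs")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelVolume
#'
#' @param labels 3D integer array (0 = background).
#' @param spacing numeric(3) voxel size in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a centred
#'   axis-aligned grid.
#' @param classNames named character vector mapping class IDs to names.
#' @return A \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(labels, spacing, affine = NULL, classNames) {
  storage.mode(labels) <- "integer"
  if (is.null(affine)) affine <- gridAffine(dim(labels), spacing)
  new("LabelVolume", labels = labels, spacing = as.numeric(spacing),
      affine = affine, classNames = classNames)
}

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  cat("LabelVolume:", paste(d, collapse = " x "), "voxels,",
      paste(signif(object@spacing, 4), collapse = " x "), "mm\n")
  ids <- sort(unique(as.vector(object@labels)))
  cat(" ", length(ids[ids != 0]), "tissue classes + background\n")
})

#' @describeIn LabelVolume-class the 3D integer label array.
#' @param x,object a \code{LabelVolume}.
#' @export
setGeneric("labels3D", function(x) standardGeneric("labels3D"))
#' @export
setMethod("labels3D", "LabelVolume", function(x) x@labels)

#' Voxel spacing in mm
#' @param x an image object.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)

#' Voxel-to-world affine
#' @param x an image object.
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))
#' @export
setMethod("voxelAffine", "LabelVolume", function(x) x@affine)

#' Class ID to name table
#' @param x a \code{LabelVolume}.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @export
setMethod("classNames", "LabelVolume", function(x) x@classNames)

## ---------------------------------------------------------------------------
## MRProtocol
## ---------------------------------------------------------------------------

#' MRProtocol: spoiled gradient echo acquisition parameters
#'
#' The MR protocol of the simulated dynamic T1-weighted spoiled gradient
#' echo acquisition: sequence timing, flip angle, acquired field of view and
#' matrix, dynamic frame timing, contrast-agent relaxivities and the target
#' pre-contrast white-matter signal-to-noise ratio used for noise
#' calibration.
#'
#' @slot tr repetition time, s.
#' @slot te echo time, s.
#' @slot flipDeg excitation flip angle, degrees.
#' @slot fovMM acquired field of view, mm, per axis
#'   (frequency-, phase-, slice-encode).
#' @slot acqMatrix acquired matrix size, voxels, per axis.
#' @slot dtS temporal resolution (frame spacing), s.
#' @slot nPre,nPost number of pre-/post-contrast frames.
#' @slot r1,r2star longitudinal / effective transverse relaxivity,
#'   per mM per s.
#' @slot snrNAWM target spatial SNR in normal-appearing white matter used to
#'   calibrate the noise level.
#'
#' @aliases MRProtocol-class
#' @exportClass MRProtocol
setClass("MRProtocol",
  representation(tr = "numeric", te = "numeric", flipDeg = "numeric",
                 fovMM = "numeric", acqMatrix = "integer", dtS = "numeric",
                 nPre = "integer", nPost = "integer",
                 r1 = "numeric", r2star = "numeric", snrNAWM = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@tr > object@te && object@te > 0))
      msg <- c(msg, "need TR > TE > 0")
    if (!(object@flipDeg > 0 && object@flipDeg < 90))
      msg <- c(msg, "flip angle must lie in (0, 90) degrees")
    if (object@nPre < 1L) msg <- c(msg, "need at least one pre-contrast frame")
    if (length(object@fovMM) != 3L || any(object@fovMM <= 0))
      msg <- c(msg, "fovMM must be 3 positive values")
    if (length(object@acqMatrix) != 3L || any(object@acqMatrix < 1L))
      msg <- c(msg, "acqMatrix must be 3 positive integers")
    if (object@dtS <= 0) msg <- c(msg, "temporal resolution must be positive")
    if (length(msg)) msg else TRUE
  })

#' Construct an MRProtocol
#'
#' @param tr,te repetition/echo time in s.
#' @param flipDeg flip angle in degrees.
#' @param fovMM field of view in mm (3 values).
#' @param acqMatrix acquired matrix (3 integers).
#' @param dtS temporal resolution in s.
#' @param nPre,nPost pre-/post-contrast frame counts.
#' @param r1,r2star relaxivities in per-mM-per-s.
#' @param snrNAWM target NAWM spatial SNR.
#' @return An \linkS4class{MRProtocol}.
#' @export
MRProtocol <- function(tr, te, flipDeg, fovMM, acqMatrix, dtS, nPre, nPost,
                       r1 = 3.9, r2star = 4.5, snrNAWM = 91.5) {
  new("MRProtocol", tr = tr, te = te, flipDeg = flipDeg,
      fovMM = as.numeric(fovMM), acqMatrix = as.integer(acqMatrix),
      dtS = dtS, nPre = as.integer(nPre), nPost = as.integer(nPost),
      r1 = r1, r2star = r2star, snrNAWM = snrNAWM)
}

setMethod("show", "MRProtocol", function(object) {
  cat(sprintf("MRProtocol: TR %.4g ms, TE %.4g ms, flip %g deg\n",
              1e3 * object@tr, 1e3 * object@te, object@flipDeg))
  cat(sprintf("  FOV %s mm, matrix %s, dt %g s, %d pre + %d post frames\n",
              paste(object@fovMM, collapse = " x "),
              paste(object@acqMatrix, collapse = " x "),
              object@dtS, object@nPre, object@nPost))
})

#' Frame mid-times of a protocol, s from the first frame
#' @param proto an \linkS4class{MRProtocol}.
#' @return numeric vector of length nPre + nPost.
#' @export
frameTimes <- function(proto) {
  (seq_len(proto@nPre + proto@nPost) - 1) * proto@dtS
}

#' Number of frames of a protocol
#' @param proto an \linkS4class{MRProtocol}.
#' @export
nFrames <- function(proto) proto@nPre + proto@nPost

#' Acquired voxel spacing of a protocol, mm
#' @param proto an \linkS4class{MRProtocol}.
#' @export
acquiredSpacing <- function(proto) proto@fovMM / proto@acqMatrix

## ---------------------------------------------------------------------------
## AIF
## ---------------------------------------------------------------------------

#' AIF: parametric arterial input function
#'
#' Plasma gadolinium concentration over time after bolus injection,
#' modelled as a biexponential decay (Weinmann-type population form) scaled
#' by the injected dose: for t past the onset,
#' cp(t) = dose * (a1 exp(-m1 t') + a2 exp(-m2 t')) with t' = t - onset,
#' and cp = 0 beforehand. Amplitudes a1, a2 are in kg/L so that cp is in mM
#' for a dose in mmol/kg; decay rates m1, m2 are per minute.
#'
#' @slot dose injected dose, mmol/kg.
#' @slot a1,a2 amplitudes, kg/L.
#' @slot m1,m2 decay rates, per minute.
#' @slot onsetS bolus arrival time, s from the start of the acquisition.
#'
#' @aliases AIF-class
#' @exportClass AIF
setClass("AIF",
  representation(dose = "numeric", a1 = "numeric", a2 = "numeric",
                 m1 = "numeric", m2 = "numeric", onsetS = "numeric"),
  validity = function(object) {
    if (object@dose < 0 || object@a1 < 0 || object@a2 < 0 ||
        object@m1 < 0 || object@m2 < 0) "AIF parameters must be non-negative"
    else TRUE
  })

#' Default population arterial input function
#'
#' Biexponential bolus-decay AIF with Weinmann population parameters,
#' representative of 0.1 mmol/kg gadoterate. The bolus arrives at the start
#' of the second frame by default (one pre-contrast frame).
#'
#' @param dose injected dose in mmol/kg.
#' @param onsetS bolus arrival in s from acquisition start.
#' @param a1,a2 amplitudes in kg/L.
#' @param m1,m2 decay rates in per-minute.
#' @return An \linkS4class{AIF}.
#' @export
defaultAIF <- function(dose = 0.1, onsetS = 73, a1 = 3.99, a2 = 4.78,
                       m1 = 0.144, m2 = 0.0111) {
  new("AIF", dose = dose, a1 = a1, a2 = a2, m1 = m1, m2 = m2, onsetS = onsetS)
}

setMethod("show", "AIF", function(object) {
  cat(sprintf(
    "AIF: biexponential, dose %g mmol/kg, onset %g s, a=(%g, %g) kg/L, m=(%g, %g) /min\n",
    object@dose, object@onsetS, object@a1, object@a2, object@m1, object@m2))
})

#' Evaluate an AIF at given times
#'
#' @param aif an \linkS4class{AIF}.
#' @param timesS numeric times in s from acquisition start.
#' @return plasma concentration in mM, zero before onset.
#' @export
aifConcentration <- function(aif, timesS) {
  tm <- (timesS - aif@onsetS) / 60   # minutes since bolus arrival
  cp <- aif@dose * (aif@a1 * exp(-aif@m1 * pmax(tm, 0)) +
                    aif@a2 * exp(-aif@m2 * pmax(tm, 0)))
  cp[tm < 0] <- 0
  cp
}

## Closed-form running integral of the biexponential AIF, mM * min.
## Independent of the trapezoidal quadrature used elsewhere; exposed for the
## package's own verification of the quadrature.
#' Exact running integral of the biexponential AIF
#' @param aif an \linkS4class{AIF}.
#' @param timesS times in s.
#' @return integral of cp from 0 to each time, in mM*min.
#' @export
aifIntegralExact <- function(aif, timesS) {
  tm <- pmax((timesS - aif@onsetS) / 60, 0)
  aif@dose * (aif@a1 / aif@m1 * (1 - exp(-aif@m1 * tm)) +
              aif@a2 / aif@m2 * (1 - exp(-aif@m2 * tm)))
}

## ---------------------------------------------------------------------------
## RigidTransform and MotionTrajectory
## ---------------------------------------------------------------------------

#' RigidTransform: 6-DOF rigid-body transform
#'
#' Rotation (degrees about x, y, z; applied in Z-Y-X order, i.e.
#' R = Rz Ry Rx) about a fixed centre in world coordinates, followed by a
#' translation in mm: y = R (x - c) + c + t.
#'
#' @slot rotDeg numeric(3) rotations about x, y, z in degrees.
#' @slot transMM numeric(3) translations in mm.
#' @slot centre numeric(3) rotation centre in world coordinates, mm.
#'
#' @aliases RigidTransform-class
#' @exportClass RigidTransform
setClass("RigidTransform",
  representation(rotDeg = "numeric", transMM = "numeric", centre = "numeric"),
  validity = function(object) {
    if (length(object@rotDeg) != 3L || length(object@transMM) != 3L ||
        length(object@centre) != 3L) "rotDeg, transMM, centre must have length 3"
    else TRUE
  })

#' Construct a RigidTransform
#' @param rotDeg rotations about x, y, z in degrees.
#' @param transMM translations in mm.
#' @param centre rotation centre in world mm.
#' @return A \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(rotDeg = c(0, 0, 0), transMM = c(0, 0, 0),
                           centre = c(0, 0, 0)) {
  new("RigidTransform", rotDeg = as.numeric(rotDeg),
      transMM = as.numeric(transMM), centre = as.numeric(centre))
}

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rot (%s) deg, trans (%s) mm, centre (%s)\n",
              paste(signif(object@rotDeg, 4), collapse = ", "),
              paste(signif(object@transMM, 4), collapse = ", "),
              paste(signif(object@centre, 4), collapse = ", ")))
})

rotationMatrixZYX <- function(rotDeg) {
  r <- rotDeg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

eulerZYXFromMatrix <- function(R) {
  ry <- -asin(max(-1, min(1, R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  c(rx, ry, rz) * 180 / pi
}

#' World-coordinate 4x4 matrix of a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @return 4x4 matrix acting on homogeneous world coordinates.
#' @export
rigidMatrix <- function(transform) {
  R <- rotationMatrixZYX(transform@rotDeg)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- transform@centre - R %*% transform@centre + transform@transMM
  M
}

#' Invert a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @return the inverse \linkS4class{RigidTransform}, same centre convention.
#' @export
rigidInverse <- function(transform) {
  R <- rotationMatrixZYX(transform@rotDeg)
  Rt <- t(R)
  ## y = R(x-c)+c+t  =>  x = Rt(y-c) + c - Rt t
  RigidTransform(rotDeg = eulerZYXFromMatrix(Rt),
                 transMM = as.numeric(-Rt %*% transform@transMM),
                 centre = transform@centre)
}

#' Compose two rigid transforms (first \code{b}, then \code{a})
#' @param a,b \linkS4class{RigidTransform} objects sharing a centre.
#' @return the composed \linkS4class{RigidTransform}.
#' @export
rigidCompose <- function(a, b) {
  M <- rigidMatrix(a) %*% rigidMatrix(b)
  R <- M[1:3, 1:3]
  c0 <- a@centre
  ## recover the translation of the centre-parameterised form
  tr <- M[1:3, 4] - c0 + R %*% c0
  RigidTransform(rotDeg = eulerZYXFromMatrix(R), transMM = as.numeric(tr),
                 centre = c0)
}

#' MotionTrajectory: one rigid transform per dynamic frame
#'
#' @slot transforms list of \linkS4class{RigidTransform}, one per frame; the
#'   first is the identity (motion is relative to the frame-1 position).
#' @slot severity one of "none", "low", "moderate", "high".
#'
#' @aliases MotionTrajectory-class
#' @exportClass MotionTrajectory
setClass("MotionTrajectory",
  representation(transforms = "list", severity = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(vapply(object@transforms, is, logical(1), "RigidTransform")))
      msg <- c(msg, "transforms must all be RigidTransform")
    if (!object@severity %in% c("none", "low", "moderate", "high"))
      msg <- c(msg, "severity must be none/low/moderate/high")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "MotionTrajectory", function(object) {
  cat(sprintf("MotionTrajectory: %d frames, severity '%s'\n",
              length(object@transforms), object@severity))
})

setMethod("length", "MotionTrajectory", function(x) length(x@transforms))

## ---------------------------------------------------------------------------
## DynamicVolume
## ---------------------------------------------------------------------------

#' DynamicVolume: 4D dynamic image with frame timing
#'
#' @slot data 4D real array (x, y, z, t).
#' @slot spacing voxel size in mm.
#' @slot frameTimes frame times in s.
#' @slot affine 4x4 voxel-to-world matrix.
#' @slot meta list of provenance (seeds, transforms, noise level, flags).
#'
#' @aliases DynamicVolume-class
#' @exportClass DynamicVolume
setClass("DynamicVolume",
  representation(data = "array", spacing = "numeric", frameTimes = "numeric",
                 affine = "matrix", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 4L) msg <- c(msg, "data must be 4D")
    if (dim(object@data)[4] != length(object@frameTimes))
      msg <- c(msg, "frame count must match frameTimes")
    if (length(object@frameTimes) > 1 && any(diff(object@frameTimes) <= 0))
      msg <- c(msg, "frameTimes must be strictly increasing")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values")
    if (length(msg)) msg else TRUE
  })

#' Construct a DynamicVolume
#' @param data 4D array (x, y, z, t).
#' @param spacing voxel size in mm.
#' @param frameTimes frame times in s.
#' @param affine optional 4x4 voxel-to-world matrix (default: centred grid).
#' @param meta optional provenance list.
#' @return A \linkS4class{DynamicVolume}.
#' @export
DynamicVolume <- function(data, spacing, frameTimes, affine = NULL,
                          meta = list()) {
  if (is.null(affine)) affine <- gridAffine(dim(data)[1:3], spacing)
  new("DynamicVolume", data = data, spacing = as.numeric(spacing),
      frameTimes = as.numeric(frameTimes), affine = affine, meta = meta)
}

setMethod("show", "DynamicVolume", function(object) {
  d <- dim(object@data)
  cat("DynamicVolume:", paste(d[1:3], collapse = " x "), "voxels x",
      d[4], "frames,", paste(signif(object@spacing, 4), collapse = " x "),
      "mm\n")
})

#' @export
setMethod("voxelSpacing", "DynamicVolume", function(x) x@spacing)
#' @export
setMethod("voxelAffine", "DynamicVolume", function(x) x@affine)

#' Extract one frame of a DynamicVolume as a 3D array
#' @param x a \linkS4class{DynamicVolume}.
#' @param i frame index.
#' @export
getFrame <- function(x, i) {
  stopifnot(is(x, "DynamicVolume"))
  x@data[, , , i, drop = TRUE]
}

## ---------------------------------------------------------------------------
## ParameterMap
## ---------------------------------------------------------------------------

#' ParameterMap: voxelwise Patlak estimates
#'
#' Voxelwise PS (per minute) and vP (fraction) maps with the per-voxel
#' fit root-mean-square residual. Negative values are permitted: they occur
#' in measured maps and carry information about artefact severity.
#'
#' @slot ps 3D array, PS in per-minute; NA outside the fitted mask.
#' @slot vp 3D array, plasma volume fraction; NA outside the fitted mask.
#' @slot residual 3D array, fit RMS residual (mM).
#' @slot framesUsed integer indices of the frames used in the fit.
#' @slot spacing voxel size, mm.
#' @slot affine 4x4 voxel-to-world matrix.
#'
#' @aliases ParameterMap-class
#' @exportClass ParameterMap
setClass("ParameterMap",
  representation(ps = "array", vp = "array", residual = "array",
                 framesUsed = "integer", spacing = "numeric",
                 affine = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@ps), dim(object@vp))) "ps and vp dims differ"
    else TRUE
  })

setMethod("show", "ParameterMap", function(object) {
  d <- dim(object@ps)
  cat("ParameterMap:", paste(d, collapse = " x "), "voxels;",
      sum(!is.na(object@ps)), "fitted;",
      length(object@framesUsed), "frames used\n")
})

#' @describeIn ParameterMap-class PS map in per-minute.
#' @param x a \code{ParameterMap}.
#' @export
setGeneric("psMap", function(x) standardGeneric("psMap"))
#' @export
setMethod("psMap", "ParameterMap", function(x) x@ps)

#' @describeIn ParameterMap-class vP map (fraction).
#' @export
setGeneric("vpMap", function(x) standardGeneric("vpMap"))
#' @export
setMethod("vpMap", "ParameterMap", function(x) x@vp)

#' @export
setMethod("voxelSpacing", "ParameterMap", function(x) x@spacing)
#' @export
setMethod("voxelAffine", "ParameterMap", function(x) x@affine)
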