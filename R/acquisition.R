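## Measurement simulation: starting-position randomisation, per-frame gross
## rigid motion, 3D Cartesian k-space resampling with FOV suppression,
## composite-k-space motion artefacts, complex Gaussian noise and magnitude
## reconstruction.
##
## Axis roles throughout: 1 = frequency encode, 2 = phase encode,
## 3 = slice/partition encode (the slowest phase-encode loop).

.INTERP_CODE <- c(nearest = 0L, linear = 1L, cubic = 2L, sinc = 3L)

#' Random starting head position
#'
#' Each of the six degrees of freedom is drawn independently and uniformly:
#' rotations over +/- \code{maxRotDeg} degrees, translations over
#' +/- \code{maxTransMM} mm. The draw uses the current RNG state; seed the
#' session (or pass a seed to the orchestrating function) for
#' reproducibility.
#'
#' @param maxRotDeg rotation half-range, degrees (default 5).
#' @param maxTransMM translation half-range, mm (default 2.5).
#' @param centre rotation centre in world mm (brain-mask centroid).
#' @return A \linkS4class{RigidTransform}.
#' @export
randomStartPosition <- function(maxRotDeg = 5, maxTransMM = 2.5,
                                centre = c(0, 0, 0)) {
  RigidTransform(rotDeg = stats::runif(3, -maxRotDeg, maxRotDeg),
                 transMM = stats::runif(3, -maxTransMM, maxTransMM),
                 centre = centre)
}

## per-step random-walk scales (sd per frame transition), by severity class;
## chosen so that the mean frame-to-frame displacement of brain voxels falls
## below 0.5 mm (low), in 0.5-1.5 mm (moderate) and above 1.5 mm (high)
.SEVERITY_SCALES <- list(
  low = c(transMM = 0.15, rotDeg = 0.15),
  moderate = c(transMM = 0.55, rotDeg = 0.55),
  high = c(transMM = 1.4, rotDeg = 1.4))

#' Generate a rigid-body motion trajectory
#'
#' A random-walk trajectory of one transform per frame (the first frame is
#' the reference, identity). Per-frame increments are Gaussian with a
#' severity-dependent scale; cumulative excursions are clamped so the head
#' stays within the field of view. Severity \code{"none"} yields identities.
#'
#' @param severity one of "none", "low", "moderate", "high".
#' @param nFrames number of frames.
#' @param centre rotation centre in world mm.
#' @param maxRotDeg,maxTransMM clamp on the cumulative excursion.
#' @return A \linkS4class{MotionTrajectory}.
#' @export
generateTrajectory <- function(severity, nFrames, centre = c(0, 0, 0),
                               maxRotDeg = 10, maxTransMM = 8) {
  severity <- match.arg(severity, c("none", "low", "moderate", "high"))
  if (severity == "none") {
    tr <- replicate(nFrames, RigidTransform(centre = centre))
    return(new("MotionTrajectory", transforms = tr, severity = severity))
  }
  sc <- .SEVERITY_SCALES[[severity]]
  rot <- matrix(0, nFrames, 3)
  tra <- matrix(0, nFrames, 3)
  for (i in seq_len(nFrames)[-1]) {
    rot[i, ] <- pmin(pmax(rot[i - 1, ] + stats::rnorm(3, 0, sc["rotDeg"]),
                          -maxRotDeg), maxRotDeg)
    tra[i, ] <- pmin(pmax(tra[i - 1, ] + stats::rnorm(3, 0, sc["transMM"]),
                          -maxTransMM), maxTransMM)
  }
  tr <- lapply(seq_len(nFrames), function(i)
    RigidTransform(rotDeg = rot[i, ], transMM = tra[i, ], centre = centre))
  new("MotionTrajectory", transforms = tr, severity = severity)
}

#' Mean frame-to-frame displacement of a trajectory
#'
#' The severity statistic: mean Euclidean displacement (mm) of a set of
#' brain points between successive frames, averaged over transitions.
#'
#' @param trajectory a \linkS4class{MotionTrajectory}.
#' @param points n x 3 matrix of world coordinates (brain voxels).
#' @return mean displacement in mm.
#' @export
trajectoryDisplacement <- function(trajectory, points) {
  tr <- trajectory@transforms
  if (length(tr) < 2) return(0)
  mats <- lapply(tr, rigidMatrix)
  d <- vapply(seq_along(tr)[-1], function(i)
    meanPointDisplacement(points, mats[[i - 1]], mats[[i]]), numeric(1))
  mean(d)
}

#' Resample a volume under a rigid-body transform
#'
#' Moves the object by \code{transform} (in world coordinates) and
#' resamples on the same grid: out(x) = in(T^-1 x). Voxels mapping outside
#' the grid are filled with 0.
#'
#' @param arr 3D array.
#' @param affine 4x4 voxel-to-world matrix of the grid.
#' @param transform a \linkS4class{RigidTransform}.
#' @param interpolation "nearest", "linear" (trilinear), "cubic"
#'   (Catmull-Rom approximation) or "sinc" (Hann-windowed, radius 4).
#' @param fill fill value for out-of-grid samples.
#' @return resampled 3D array.
#' @export
applyRigid <- function(arr, affine, transform,
                       interpolation = c("linear", "nearest", "cubic", "sinc"),
                       fill = 0) {
  interpolation <- match.arg(interpolation)
  Tm <- rigidMatrix(transform)
  M <- solve(affine) %*% solve(Tm) %*% affine
  d <- dim(arr)
  .resampleAffineC(as.numeric(arr), as.integer(d), as.integer(d),
                   M[1:3, , drop = FALSE], .INTERP_CODE[[interpolation]], fill)
}

#' Resample a volume onto another grid
#'
#' General grid-to-grid resampling through world coordinates, with an
#' optional world-space rigid transform applied to the object:
#' out(x) = src(T^-1 x).
#'
#' @param src 3D array on the source grid.
#' @param srcAffine source 4x4 voxel-to-world matrix.
#' @param outDim output grid size.
#' @param outAffine output 4x4 voxel-to-world matrix.
#' @param transform optional \linkS4class{RigidTransform} moving the object.
#' @param interpolation see \code{\link{applyRigid}}.
#' @param fill fill value.
#' @return 3D array of size \code{outDim}.
#' @export
resampleToGrid <- function(src, srcAffine, outDim, outAffine,
                           transform = NULL,
                           interpolation = c("linear", "nearest", "cubic", "sinc"),
                           fill = 0) {
  interpolation <- match.arg(interpolation)
  W <- if (is.null(transform)) diag(4) else solve(rigidMatrix(transform))
  M <- solve(srcAffine) %*% W %*% outAffine
  .resampleAffineC(as.numeric(src), as.integer(dim(src)), as.integer(outDim),
                   M[1:3, , drop = FALSE], .INTERP_CODE[[interpolation]], fill)
}

## Suppress signal outside the acquired FOV along the frequency- (1) and
## slice-encode (3) axes: band filtering and slab-selective excitation.
## The phase-encode axis is deliberately left free to alias.
maskToFOV <- function(arr, affine, fovMM, axes = c(1L, 3L)) {
  d <- dim(arr)
  for (a in axes) {
    w <- axisWorld(d, affine, a)
    out <- abs(w) > fovMM[a] / 2 + 1e-9
    if (!any(out)) next
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    idx[[a]] <- which(out)
    arr[idx[[1]], idx[[2]], idx[[3]]] <- 0
  }
  arr
}

#' Sample the k-space of a high-resolution frame at acquired resolution
#'
#' Forms the 3D Cartesian k-space of the frame (unitary FFT), suppresses
#' signal outside the acquired FOV along the frequency- and slice-encode
#' axes beforehand, and extracts the central k-space block corresponding to
#' the acquired matrix (low-pass truncation; DC at the centre index
#' floor(N/2) of the shifted layout). The source grid must cover the same
#' FOV as the protocol.
#'
#' @param frame high-resolution 3D array.
#' @param spacing source voxel size, mm.
#' @param proto an \linkS4class{MRProtocol}.
#' @return complex 3D array of size \code{proto@acqMatrix}, scaled so that
#'   a unitary inverse FFT reproduces image intensities on the acquired
#'   grid.
#' @export
sampleKspace <- function(frame, spacing, proto) {
  d <- dim(frame)
  fovSrc <- d * spacing
  if (any(abs(fovSrc - proto@fovMM) > 1e-6 * proto@fovMM))
    stop("source grid FOV (", paste(signif(fovSrc, 6), collapse = " x "),
         " mm) must match the protocol FOV")
  if (any(proto@acqMatrix > d))
    stop("acquired matrix exceeds the source matrix")
  A <- gridAffine(d, spacing)
  frame <- maskToFOV(frame, A, proto@fovMM)
  K <- fftU(frame)
  Kc <- cropKspaceCentred(K, proto@acqMatrix)
  ## Cropping alone yields samples aligned with the first source sample; a
  ## half-voxel-difference phase ramp re-centres them on the centred
  ## acquired grid used by every affine in the package.
  spA <- acquiredSpacing(proto)
  for (a in 1:3) {
    n <- proto@acqMatrix[a]
    kk <- c(0:(ceiling(n / 2) - 1), -(n - ceiling(n / 2)):-1)
    delta <- (spA[a] - spacing[a]) / 2
    ramp <- exp(2i * pi * kk * delta / proto@fovMM[a])
    dm <- c(1L, 1L, 1L); dm[a] <- n
    perm <- order(c(a, setdiff(1:3, a)))
    Kc <- Kc * aperm(array(ramp, c(n, proto@acqMatrix[setdiff(1:3, a)])), perm)
  }
  Kc * sqrt(prod(proto@acqMatrix) / prod(d))
}

#' Composite k-space of two head positions (motion artefact)
#'
#' Mixes two co-registered k-space frames of the same scene: lines below the
#' split (in sequential bottom-to-top acquisition order along the chosen
#' phase-encode axis) come from the initial-position k-space, the rest from
#' the subsequent-position k-space. Ghosting, ringing and blurring in the
#' reconstruction follow from the inter-position inconsistency.
#'
#' @param kInitial,kSubsequent complex k-space arrays of identical shape.
#' @param splitFraction fraction in [0, 1] of lines taken from
#'   \code{kInitial}.
#' @param axis phase-encode axis the split runs along (default 3, the
#'   slowest partition-encode loop).
#' @return composite complex k-space array.
#' @export
compositeMotionKspace <- function(kInitial, kSubsequent, splitFraction,
                                  axis = 3L) {
  if (!identical(dim(kInitial), dim(kSubsequent))) stop("k-space shape mismatch")
  stopifnot(splitFraction >= 0, splitFraction <= 1)
  n <- dim(kInitial)[axis]
  nInit <- round(splitFraction * n)
  out <- kSubsequent
  if (nInit > 0) {
    ord <- fftshiftIdx(n)            # bottom-to-top line order
    take <- ord[seq_len(nInit)]
    idx <- list(quote(expr =), quote(expr =), quote(expr =))
    idx[[axis]] <- take
    out[idx[[1]], idx[[2]], idx[[3]]] <- kInitial[idx[[1]], idx[[2]], idx[[3]]]
  }
  out
}

#' Add complex Gaussian noise and reconstruct the magnitude image
#'
#' Uncorrelated white Gaussian noise of standard deviation \code{sigma} is
#' added to the real and imaginary channels of the sampled k-space; a 3D
#' inverse (unitary) Fourier transform and voxelwise magnitude yield the
#' acquired image. Under the unitary convention \code{sigma} is also the
#' per-channel image-domain noise level, so background voxels follow a
#' Rayleigh law with scale \code{sigma} and low-signal voxels are Rician.
#'
#' @param k complex 3D k-space array.
#' @param sigma noise standard deviation (image-domain units), >= 0.
#' @return real 3D magnitude array.
#' @export
addNoiseAndReconstruct <- function(k, sigma) {
  stopifnot(sigma >= 0)
  if (sigma > 0) {
    n <- length(k)
    k <- k + complex(real = stats::rnorm(n, 0, sigma),
                     imaginary = stats::rnorm(n, 0, sigma))
  }
  Mod(ifftU(k))
}

#' Brain-mask centroid in world coordinates
#'
#' Centroid of the parenchymal brain classes (NAWM, WMH, stroke, cortical
#' and subcortical GM), the rotation-centre convention of the simulator.
#'
#' @param vol a \linkS4class{LabelVolume}.
#' @return numeric(3) world coordinates, mm.
#' @export
brainCentroid <- function(vol) {
  ids <- as.integer(names(vol@classNames)[vol@classNames %in% BRAIN_CLASSES])
  idx <- which(array(vol@labels %in% ids, dim(vol@labels)), arr.ind = TRUE)
  if (nrow(idx) == 0) return(c(0, 0, 0))
  v <- colMeans(idx) - 1
  as.numeric(vol@affine %*% c(v, 1))[1:3]
}

#' Calibrate the k-space noise level to a target NAWM SNR
#'
#' Reconstructs the noise-free pre-contrast frame, measures the mean NAWM
#' signal within an eroded propagated mask, and returns
#' sigma = mean / SNR, the noise level at which the NAWM spatial SNR of the
#' reconstruction equals the protocol's target.
#'
#' @param vol a \linkS4class{LabelVolume}.
#' @param table a \code{\link{tissueParameterTable}}.
#' @param aif an \linkS4class{AIF}.
#' @param proto an \linkS4class{MRProtocol}.
#' @param start optional \linkS4class{RigidTransform} starting position.
#' @param erodeRadius erosion radius (voxels) for the NAWM mask.
#' @return sigma, with attributes \code{nawmMean} and \code{mask}.
#' @export
calibrateNoiseSigma <- function(vol, table, aif, proto, start = NULL,
                                erodeRadius = 1L) {
  f1 <- droFrameFun(vol, table, aif, proto)(1L)
  if (!is.null(start)) f1 <- applyRigid(f1, vol@affine, start)
  recon <- Mod(ifftU(sampleKspace(f1, vol@spacing, proto)))
  acqA <- gridAffine(proto@acqMatrix, acquiredSpacing(proto))
  nawmId <- as.integer(names(vol@classNames)[vol@classNames == "nawm"])
  m <- resampleToGrid((vol@labels == nawmId) * 1, vol@affine,
                      proto@acqMatrix, acqA, transform = start) > 0.5
  m <- erodeMask(m, erodeRadius)
  if (!any(m)) stop("eroded NAWM mask is empty at acquired resolution")
  mu <- mean(recon[m])
  structure(mu / proto@snrNAWM, nawmMean = mu, mask = m)
}

#' Simulate the DCE-MRI acquisition of the phantom
#'
#' Orchestrates the five acquisition steps per frame: position the object
#' (starting position composed with the gross-motion trajectory), form the
#' k-space at the current and, when motion artefacts are enabled, the next
#' position, composite them at a random split, truncate to the acquired
#' matrix, add complex Gaussian noise, and reconstruct the magnitude image.
#'
#' @param vol a \linkS4class{LabelVolume} (high-resolution ground truth).
#' @param table a \code{\link{tissueParameterTable}}.
#' @param aif an \linkS4class{AIF}.
#' @param proto an \linkS4class{MRProtocol}.
#' @param trajectory a \linkS4class{MotionTrajectory}, or NULL to generate
#'   one of the given \code{severity}.
#' @param severity trajectory severity when \code{trajectory} is NULL.
#' @param start a \linkS4class{RigidTransform}, or NULL to draw one when
#'   the startPosition flag is on.
#' @param flags named logical list: \code{startPosition},
#'   \code{grossMotion}, \code{motionArtefacts}, \code{noise}. k-space
#'   sampling at the acquired matrix is always performed.
#' @param sigma noise level; NULL calibrates it from the protocol's NAWM
#'   SNR via \code{\link{calibrateNoiseSigma}}.
#' @param interpolation interpolation used to move the object.
#' @param seed integer seed; all randomness (start, trajectory, splits,
#'   noise) is drawn from it.
#' @param extracerebralOn toggle extra-cerebral enhancement.
#' @return A \linkS4class{DynamicVolume} on the acquired grid; the
#'   \code{meta} slot records the start position, trajectory, noise level
#'   and split fractions.
#' @export
simulateAcquisition <- function(vol, table, aif, proto, trajectory = NULL,
                                severity = "moderate", start = NULL,
                                flags = list(), sigma = NULL,
                                interpolation = "linear", seed = NULL,
                                extracerebralOn = TRUE) {
  fl <- utils::modifyList(list(startPosition = TRUE, grossMotion = TRUE,
                               motionArtefacts = TRUE, noise = TRUE), flags)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nFrames(proto)
  ctr <- brainCentroid(vol)
  if (is.null(start))
    start <- if (fl$startPosition) randomStartPosition(centre = ctr)
             else RigidTransform(centre = ctr)
  if (is.null(trajectory))
    trajectory <- generateTrajectory(if (fl$grossMotion) severity else "none",
                                     n, centre = ctr)
  if (length(trajectory) != n) stop("trajectory length must equal frame count")
  if (!fl$grossMotion && trajectory@severity != "none")
    trajectory <- generateTrajectory("none", n, centre = ctr)
  splits <- if (fl$motionArtefacts) stats::runif(n) else rep(0, n)
  if (is.null(sigma))
    sigma <- if (fl$noise)
      as.numeric(calibrateNoiseSigma(vol, table, aif, proto, start = start))
      else 0
  if (!fl$noise) sigma <- 0

  frameAt <- droFrameFun(vol, table, aif, proto, extracerebralOn = extracerebralOn)
  pos <- lapply(trajectory@transforms, function(g) rigidCompose(g, start))
  isIdentity <- function(tr) all(abs(c(tr@rotDeg, tr@transMM)) < 1e-12)

  acq <- array(0, c(proto@acqMatrix, n))
  for (t in seq_len(n)) {
    f <- frameAt(t)
    ft <- if (isIdentity(pos[[t]])) f
          else applyRigid(f, vol@affine, pos[[t]], interpolation)
    kt <- sampleKspace(ft, vol@spacing, proto)
    if (fl$motionArtefacts && t < n && splits[t] < 1) {
      moved <- !identical(trajectory@transforms[[t]]@rotDeg,
                          trajectory@transforms[[t + 1]]@rotDeg) ||
               !identical(trajectory@transforms[[t]]@transMM,
                          trajectory@transforms[[t + 1]]@transMM)
      if (moved) {
        fn <- if (isIdentity(pos[[t + 1]])) f
              else applyRigid(f, vol@affine, pos[[t + 1]], interpolation)
        kn <- sampleKspace(fn, vol@spacing, proto)
        kt <- compositeMotionKspace(kt, kn, splits[t])
      }
    }
    acq[, , , t] <- addNoiseAndReconstruct(kt, sigma)
  }
  DynamicVolume(acq, spacing = acquiredSpacing(proto),
                frameTimes = frameTimes(proto),
                affine = gridAffine(proto@acqMatrix, acquiredSpacing(proto)),
                meta = list(start = start, trajectory = trajectory,
                            sigma = sigma, splits = splits, flags = fl,
                            centre = ctr))
}
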