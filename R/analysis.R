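## Measurement pipeline: rigid realignment of the dynamic series,
## enhancement and concentration computation, and voxelwise Patlak fitting.

## mean-pool by 2 along each axis (multi-resolution registration level)
.poolHalf <- function(arr) {
  d <- dim(arr) %/% 2 * 2
  arr <- arr[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  a <- array(arr, c(2, d[1] / 2, 2, d[2] / 2, 2, d[3] / 2))
  apply(a, c(2, 4, 6), mean)
}

## separable Gaussian smoothing via k-space (periodic boundary)
.gaussSmooth <- function(arr, sigmaVox) {
  if (sigmaVox <= 0) return(arr)
  d <- dim(arr)
  g <- lapply(1:3, function(a)
    exp(-2 * (pi * freqFraction(d[a]) / 2 * sigmaVox)^2))
  G <- array(g[[1]], d) *
       aperm(array(g[[2]], d[c(2, 1, 3)]), c(2, 1, 3)) *
       aperm(array(g[[3]], d[c(3, 1, 2)]), c(2, 3, 1))
  Re(ifftU(fftU(arr) * G))
}

## negative normalised cross-correlation between fixed and the moved image
.nccCost <- function(par, moving, fixed, affine, centre, mask, interpolation) {
  tr <- RigidTransform(rotDeg = par[1:3], transMM = par[4:6], centre = centre)
  mv <- applyRigid(moving, affine, tr, interpolation)
  a <- mv[mask]; b <- fixed[mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  -stats::cor(a, b)
}

#' Rigid intramodal registration
#'
#' Estimates the 6-DOF transform that moves \code{moving} onto
#' \code{fixed} by maximising normalised cross-correlation with a two-level
#' multi-resolution search (quasi-Newton descent with a simplex polish at
#' each level).
#'
#' @param moving,fixed 3D arrays on the same grid.
#' @param affine 4x4 voxel-to-world matrix of the grid.
#' @param centre rotation centre, world mm.
#' @param init optional initial \linkS4class{RigidTransform}.
#' @param interpolation interpolation used inside the similarity cost;
#'   cubic gives a smoother cost surface and markedly lower sub-voxel bias
#'   than trilinear.
#' @param levels number of resolution levels (2 = half + full).
#' @param smoothVox Gaussian pre-smoothing (voxels) applied to both images
#'   before the search. Without it the cost rewards any transform whose
#'   resampling blurs the moving image (it suppresses
#'   enhancement-driven frame differences), biasing motion-free series
#'   toward spurious rotations; a light common blur removes that reward
#'   while keeping the optimum sharp.
#' @return A \linkS4class{RigidTransform} such that
#'   \code{applyRigid(moving, affine, result)} is aligned with
#'   \code{fixed}; attribute \code{"converged"} reports optimiser status.
#' @export
registerRigid <- function(moving, fixed, affine, centre = c(0, 0, 0),
                          init = NULL, interpolation = "cubic", levels = 2L,
                          smoothVox = 0.6) {
  par <- if (is.null(init)) rep(0, 6) else c(init@rotDeg, init@transMM)
  ok <- TRUE
  moving <- .gaussSmooth(moving, smoothVox)
  fixed <- .gaussSmooth(fixed, smoothVox)
  grids <- list(list(mov = moving, fix = fixed, aff = affine))
  if (levels >= 2L && all(dim(moving) >= 16L)) {
    affH <- affine
    affH[1:3, 1:3] <- affH[1:3, 1:3] * 2
    affH[1:3, 4] <- affine[1:3, 4] +
      as.numeric(affine[1:3, 1:3] %*% rep(0.5, 3)) # pooled voxel centres
    grids <- c(list(list(mov = .poolHalf(moving), fix = .poolHalf(fixed),
                         aff = affH)), grids)
  }
  for (g in grids) {
    mask <- g$fix > 0.05 * max(g$fix)
    if (sum(mask) < 50) mask <- array(TRUE, dim(g$fix))
    res <- tryCatch({
      ## quasi-Newton descent followed by a simplex polish: the gradient
      ## step finds the basin, the simplex is robust to the residual
      ## interpolation scalloping of the cost
      o1 <- stats::optim(par, .nccCost, moving = g$mov, fixed = g$fix,
                         affine = g$aff, centre = centre, mask = mask,
                         interpolation = interpolation, method = "BFGS",
                         control = list(maxit = 40, reltol = 1e-10))
      stats::optim(o1$par, .nccCost, moving = g$mov, fixed = g$fix,
                   affine = g$aff, centre = centre, mask = mask,
                   interpolation = interpolation, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-9))
    }, error = function(e) NULL)
    if (is.null(res)) { ok <- FALSE; break }
    par <- res$par
  }
  out <- RigidTransform(rotDeg = par[1:3], transMM = par[4:6], centre = centre)
  attr(out, "converged") <- ok
  out
}

#' Spatially realign the frames of a dynamic series
#'
#' Registration mode estimates a 6-DOF transform per frame against the
#' first (pre-contrast) frame by intensity-based rigid registration and
#' resamples each frame accordingly. Oracle mode inverts the known
#' simulation trajectory (available for simulated data), isolating
#' interpolation effects from registration error. A frame whose optimiser
#' fails is left unresampled with a warning.
#'
#' @param series a \linkS4class{DynamicVolume}.
#' @param mode "registration" or "oracle".
#' @param interpolation "linear" (trilinear) or "sinc" for the final
#'   resampling.
#' @param trajectory the true \linkS4class{MotionTrajectory} (oracle mode);
#'   defaults to the one recorded in \code{series@meta}.
#' @return A realigned \linkS4class{DynamicVolume}; the applied transforms
#'   are stored in \code{meta$realignTransforms}.
#' @export
realignFrames <- function(series, mode = c("registration", "oracle"),
                          interpolation = c("linear", "sinc"),
                          trajectory = NULL) {
  mode <- match.arg(mode)
  interpolation <- match.arg(interpolation)
  n <- dim(series@data)[4]
  A <- series@affine
  centre <- series@meta$centre %||% c(0, 0, 0)
  if (mode == "oracle") {
    trajectory <- trajectory %||% series@meta$trajectory
    if (is.null(trajectory)) stop("oracle mode requires the true trajectory")
    transforms <- lapply(trajectory@transforms, rigidInverse)
  } else {
    fixed <- getFrame(series, 1)
    transforms <- vector("list", n)
    transforms[[1]] <- RigidTransform(centre = centre)
    for (t in seq_len(n)[-1]) {
      tr <- registerRigid(getFrame(series, t), fixed, A, centre = centre,
                          init = if (t > 2) transforms[[t - 1]] else NULL)
      if (!isTRUE(attr(tr, "converged"))) {
        warning("registration failed for frame ", t, "; identity used")
        tr <- RigidTransform(centre = centre)
      }
      transforms[[t]] <- tr
    }
  }
  out <- series@data
  for (t in seq_len(n)) {
    tr <- transforms[[t]]
    if (all(abs(c(tr@rotDeg, tr@transMM)) < 1e-12)) next
    out[, , , t] <- applyRigid(getFrame(series, t), A, tr, interpolation)
  }
  meta <- series@meta
  meta$realignTransforms <- transforms
  meta$realignMode <- mode
  DynamicVolume(out, spacing = series@spacing, frameTimes = series@frameTimes,
                affine = A, meta = meta)
}

#' Convert a dynamic signal series to gadolinium concentration
#'
#' Per voxel: enhancement relative to the pre-contrast mean, inversion of
#' the SPGR signal equation for T1[t] given the nominal flip angle, TR and
#' the regional T10, then C_t = (1/T1[t] - 1/T10) / r1. The T2* factor at
#' the echo time is neglected by default (the forward model retains it, so
#' the mismatch is a real, documented error source); setting
#' \code{t2starCorrection} applies a two-pass first-order correction using
#' the nominal r2*. Voxels whose enhancement exceeds the SPGR ceiling are
#' clamped and flagged.
#'
#' @param series a \linkS4class{DynamicVolume}.
#' @param T10map 3D array of pre-contrast T1 (s) at acquired resolution;
#'   non-positive or NA entries mark voxels excluded from conversion.
#' @param proto an \linkS4class{MRProtocol}.
#' @param method "spgr" (full inversion) or "linear" (first-order
#'   enhancement-proportional-to-concentration diagnostic path).
#' @param t2starCorrection logical; compensate the neglected T2* decay.
#' @return 4D concentration array (mM); attribute \code{"clamped"} is the
#'   logical mask of voxels clamped at the ceiling in any frame.
#' @export
signalToConcentration <- function(series, T10map, proto,
                                  method = c("spgr", "linear"),
                                  t2starCorrection = FALSE) {
  method <- match.arg(method)
  d <- dim(series@data)
  n <- d[4]
  V <- prod(d[1:3])
  S <- matrix(series@data, V, n)
  pre <- seq_len(proto@nPre)
  preMean <- rowMeans(S[, pre, drop = FALSE])
  T10 <- as.numeric(T10map)
  valid <- is.finite(T10) & T10 > 0 & is.finite(preMean) & preMean > 0
  E <- S / preMean   # enhancement
  th <- proto@flipDeg * pi / 180
  s <- sin(th); cth <- cos(th)
  f0 <- spgrSaturation(T10, proto)
  clamped <- rep(FALSE, V)

  invertOnce <- function(E) {
    F <- E * f0
    hi <- is.finite(F) & F >= s * (1 - 1e-9)
    F[hi] <- s * (1 - 1e-9)
    F[F < 1e-12] <- 1e-12
    x <- (s - F) / (s - F * cth)
    T1 <- -proto@tr / log(x)
    list(C = (1 / T1 - 1 / T10) / proto@r1, hi = hi)
  }

  if (method == "linear") {
    ## first-order: dln(S)/dR1 at T10 maps enhancement to concentration
    E1 <- exp(-proto@tr / T10)
    dlnS <- proto@tr * E1 * (1 / (1 - E1) - cth / (1 - cth * E1))
    C <- (E - 1) * (1 / (proto@r1 * dlnS))
  } else {
    res <- invertOnce(E)
    C <- res$C
    clamped <- clamped | rowSums(matrix(res$hi, V, n)) > 0
    if (t2starCorrection) {
      Ec <- E * exp(proto@te * proto@r2star * pmax(C, 0))
      res <- invertOnce(Ec)
      Ec <- E * exp(proto@te * proto@r2star * pmax(res$C, 0))
      res <- invertOnce(Ec)
      C <- res$C
    }
  }
  C[!valid, ] <- NA_real_
  out <- array(C, d)
  attr(out, "clamped") <- array(clamped & valid, d[1:3])
  out
}

#' Fit the Patlak model by multiple linear regression
#'
#' Ordinary least squares of C_t[t] on the regressors c_p[t] and
#' integral(c_p, 0..t) without intercept (the Patlak equation has no offset
#' term), over the non-excluded frames. The integral uses the same
#' cumulative trapezoidal quadrature as the forward model, so fitting
#' noise-free forward-model output recovers (vP, PS) exactly. The first
#' three post-contrast frames are omitted by default, replicating the
#' in-vivo analysis.
#'
#' @param C concentration: a numeric vector of length nFrames, or a matrix
#'   with frames in rows (nFrames x nVoxels).
#' @param aif an \linkS4class{AIF}.
#' @param timesS frame times, s.
#' @param nPre number of pre-contrast frames.
#' @param excludePost number of initial post-contrast frames to omit.
#' @param intercept include an offset term (sensitivity analyses only).
#' @return list with \code{vP}, \code{PS} (per minute), \code{residual}
#'   (RMS, mM) and \code{framesUsed}.
#' @export
patlakFit <- function(C, aif, timesS, nPre = 1L, excludePost = 3L,
                      intercept = FALSE) {
  cp <- aifConcentration(aif, timesS)
  if (all(cp == 0)) stop("rank-deficient design: AIF is identically zero")
  intg <- cumtrapz(cp, timesS / 60)
  n <- length(timesS)
  excl <- if (excludePost > 0) nPre + seq_len(excludePost) else integer()
  keep <- setdiff(seq_len(n), excl)
  if (length(keep) < 3L) stop("fewer than 3 frames remain after exclusion")
  X <- cbind(vP = cp, PS = intg)
  if (intercept) X <- cbind(X, offset = 1)
  Xk <- X[keep, , drop = FALSE]
  if (qr(Xk)$rank < ncol(Xk)) stop("rank-deficient design")
  single <- is.null(dim(C))
  Cm <- if (single) matrix(C, ncol = 1) else C
  stopifnot(nrow(Cm) == n)
  XtX <- crossprod(Xk)
  beta <- solve(XtX, crossprod(Xk, Cm[keep, , drop = FALSE]))
  fitted <- Xk %*% beta
  rss <- colSums((Cm[keep, , drop = FALSE] - fitted)^2)
  list(vP = as.numeric(beta["vP", ]), PS = as.numeric(beta["PS", ]),
       residual = sqrt(rss / length(keep)), framesUsed = keep)
}

#' Voxelwise Patlak parameter maps
#'
#' Composes \code{\link{signalToConcentration}} and \code{\link{patlakFit}}
#' per voxel over the non-background mask. Per-voxel failures (e.g.
#' enhancement beyond the SPGR ceiling) are flagged, never fatal.
#'
#' @param series a (realigned or raw) \linkS4class{DynamicVolume}.
#' @param T10map 3D array of regional T10 (s); NA or <= 0 marks background.
#' @param aif an \linkS4class{AIF}.
#' @param proto an \linkS4class{MRProtocol}.
#' @param mask optional logical 3D array restricting the fit.
#' @param excludePost initial post-contrast frames to omit.
#' @param method,t2starCorrection see \code{\link{signalToConcentration}}.
#' @return A \linkS4class{ParameterMap}.
#' @export
fitParameterMaps <- function(series, T10map, aif, proto, mask = NULL,
                             excludePost = 3L, method = "spgr",
                             t2starCorrection = FALSE) {
  d <- dim(series@data)
  C <- signalToConcentration(series, T10map, proto, method = method,
                             t2starCorrection = t2starCorrection)
  if (is.null(mask)) mask <- is.finite(T10map) & T10map > 0
  V <- prod(d[1:3])
  Cm <- t(matrix(C, V, d[4]))          # frames x voxels
  idx <- which(as.vector(mask) & colSums(!is.finite(Cm)) == 0)
  fit <- patlakFit(Cm[, idx, drop = FALSE], aif, series@frameTimes,
                   nPre = proto@nPre, excludePost = excludePost)
  ps <- vp <- resid <- array(NA_real_, d[1:3])
  ps[idx] <- fit$PS
  vp[idx] <- fit$vP
  resid[idx] <- fit$residual
  new("ParameterMap", ps = ps, vp = vp, residual = resid,
      framesUsed = as.integer(fit$framesUsed), spacing = series@spacing,
      affine = series@affine)
}
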