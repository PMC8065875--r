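## Segmentation propagation, T10 map construction, post-processing (mask
## erosion, k-space low-pass filtering), the four summary estimators and
## the Monte-Carlo experiment harness.

#' Morphological erosion with a spherical structuring element
#'
#' Erodes a binary mask with a sphere of the given radius in voxels
#' (offsets with Euclidean norm <= radius). Voxels outside the grid count
#' as background, so the mask also erodes at the grid boundary. An empty
#' result is allowed (and flagged with a warning by callers that need a
#' non-empty mask).
#'
#' @param mask logical 3D array.
#' @param radius structuring-element radius in voxels (default 1).
#' @return eroded logical array, always a subset of \code{mask}.
#' @export
erodeMask <- function(mask, radius = 1L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, radius >= 0)
  if (radius == 0) return(mask)
  r <- floor(radius)
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= radius^2, ]
  d <- dim(mask)
  out <- mask
  shift1 <- function(m, o) {
    res <- array(FALSE, d)
    src <- dst <- vector("list", 3)
    for (a in 1:3) {
      if (o[a] >= 0) { dst[[a]] <- seq_len(d[a] - o[a]) + o[a]
                       src[[a]] <- seq_len(d[a] - o[a]) }
      else           { dst[[a]] <- seq_len(d[a] + o[a])
                       src[[a]] <- seq_len(d[a] + o[a]) - o[a] }
      if (length(dst[[a]]) == 0) return(res)
    }
    res[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    res
  }
  for (i in seq_len(nrow(offs))) {
    o <- as.integer(offs[i, ])
    if (all(o == 0)) next
    out <- out & shift1(mask, -o)
  }
  out
}

#' Propagate the tissue segmentation to acquired space
#'
#' Registers the high-resolution pre-contrast T1-weighted image to the
#' acquired pre-contrast frame (or takes the known simulation start
#' position in oracle mode), resamples each binary class mask with cubic
#' interpolation into a soft probability at acquired resolution, and labels
#' each voxel with the class of maximum probability; voxels where every
#' probability is below 0.5 become background.
#'
#' @param vol the high-resolution \linkS4class{LabelVolume}.
#' @param series the acquired \linkS4class{DynamicVolume} (frame 1 is the
#'   registration target).
#' @param table a \code{\link{tissueParameterTable}} (needed to synthesise
#'   the high-resolution T1w image in registration mode).
#' @param aif an \linkS4class{AIF} (registration mode).
#' @param proto an \linkS4class{MRProtocol}.
#' @param mode "registration" or "oracle" (use the known start transform).
#' @param transform optional \linkS4class{RigidTransform} overriding the
#'   oracle transform (defaults to \code{series@meta$start}).
#' @return integer 3D label array at acquired resolution; the transform
#'   used is attached as attribute \code{"transform"}.
#' @export
propagateSegmentation <- function(vol, series, table = NULL, aif = NULL,
                                  proto = NULL,
                                  mode = c("oracle", "registration"),
                                  transform = NULL) {
  mode <- match.arg(mode)
  acqDim <- dim(series@data)[1:3]
  acqA <- series@affine
  if (mode == "oracle") {
    tr <- transform %||% series@meta$start
    if (is.null(tr)) stop("oracle mode requires the start transform")
  } else {
    if (is.null(table) || is.null(aif) || is.null(proto))
      stop("registration mode needs table, aif and proto to synthesise the T1w image")
    t1w <- droFrameFun(vol, table, aif, proto)(1L)
    movingAcq <- resampleToGrid(t1w, vol@affine, acqDim, acqA)
    tr <- registerRigid(movingAcq, getFrame(series, 1), acqA,
                        centre = series@meta$centre %||% c(0, 0, 0))
    if (!isTRUE(attr(tr, "converged"))) stop("segmentation registration failed")
  }
  ids <- as.integer(names(vol@classNames))
  prob <- array(0, c(acqDim, length(ids)))
  for (i in seq_along(ids)) {
    m <- (vol@labels == ids[i]) * 1
    prob[, , , i] <- resampleToGrid(m, vol@affine, acqDim, acqA,
                                    transform = tr, interpolation = "cubic")
  }
  best <- apply(prob, 1:3, which.max)
  pmax3 <- apply(prob, 1:3, max)
  out <- array(ids[best], acqDim)
  out[pmax3 < 0.5] <- 0L
  storage.mode(out) <- "integer"
  attr(out, "transform") <- tr
  out
}

#' Build a regional T10 map at acquired resolution
#'
#' Piecewise-constant pre-contrast T1 per propagated tissue class;
#' background voxels get NA (excluded from fitting).
#'
#' @param labelMap integer 3D label array at acquired resolution.
#' @param table a \code{\link{tissueParameterTable}} covering every label.
#' @return 3D array of T10 in s, NA in background.
#' @export
buildT10Map <- function(labelMap, table) {
  ids <- setdiff(sort(unique(as.vector(labelMap))), 0L)
  missing <- setdiff(ids, table$class_id)
  if (length(missing))
    stop("no T10 for class(es): ", paste(missing, collapse = ", "))
  lut <- rep(NA_real_, max(table$class_id) + 1)
  lut[table$class_id + 1] <- table$T10_s
  array(lut[as.vector(labelMap) + 1L], dim(labelMap))
}

## ---------------------------------------------------------------------------
## Bessel k-space low-pass filter
## ---------------------------------------------------------------------------

## reverse Bessel polynomial coefficients, ascending powers
.reverseBesselCoef <- function(n) {
  k <- 0:n
  factorial(2 * n - k) / (2^(n - k) * factorial(k) * factorial(n - k))
}

#' Magnitude response of a Bessel low-pass filter
#'
#' |H(j w)| = theta_n(0) / |theta_n(j w)| with theta_n the reverse Bessel
#' polynomial, frequency-scaled so the -3 dB point falls at
#' \code{u = cutoff}. A Bessel response is monotone with unit DC gain,
#' which is what the ringing-mitigation experiment requires.
#'
#' @param u normalised spatial frequency as a fraction of Nyquist (>= 0).
#' @param order filter order (default 4).
#' @param cutoff -3 dB cutoff as a fraction of Nyquist, in (0, 1].
#' @return magnitude response at each \code{u}.
#' @export
besselLowpassResponse <- function(u, order = 4L, cutoff = 0.7) {
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must lie in (0, 1]")
  a <- .reverseBesselCoef(order)
  mag <- function(w) {
    s <- 1i * w
    h <- vapply(s, function(si) Mod(sum(a * si^(0:order))), numeric(1))
    a[1] / h
  }
  ## -3 dB frequency of the unit-scaled polynomial
  w3 <- stats::uniroot(function(w) mag(w) - 1 / sqrt(2),
                       c(1e-6, 10 * (order + 1)))$root
  mag(abs(u) / cutoff * w3)
}

#' Low-pass filter a dynamic series in k-space
#'
#' Each frame is Fourier-transformed, multiplied by a separable per-axis
#' low-pass magnitude response (Bessel by default) and inverse-transformed;
#' the response is real and even, so the output is real. The DC gain is 1,
#' preserving the mean of every frame.
#'
#' @param series a \linkS4class{DynamicVolume}.
#' @param order Bessel filter order.
#' @param cutoff -3 dB cutoff as a fraction of Nyquist, in (0, 1].
#' @param response optional custom response function \code{f(u)} of the
#'   normalised frequency, replacing the Bessel response.
#' @return the filtered \linkS4class{DynamicVolume}.
#' @export
lowpassFilterKspace <- function(series, order = 4L, cutoff = 0.7,
                                response = NULL) {
  d <- dim(series@data)
  g <- lapply(1:3, function(a) {
    u <- abs(freqFraction(d[a]))
    if (is.null(response)) besselLowpassResponse(u, order, cutoff)
    else response(u)
  })
  G <- array(g[[1]], d[1:3]) *
       aperm(array(g[[2]], d[c(2, 1, 3)]), c(2, 1, 3)) *
       aperm(array(g[[3]], d[c(3, 1, 2)]), c(2, 3, 1))
  out <- series@data
  for (t in seq_len(d[4]))
    out[, , , t] <- Re(ifftU(fftU(getFrame(series, t)) * G))
  DynamicVolume(out, spacing = series@spacing, frameTimes = series@frameTimes,
                affine = series@affine, meta = series@meta)
}

## ---------------------------------------------------------------------------
## Summary estimators
## ---------------------------------------------------------------------------

#' Ground-truth (PS, vP) per class from the tissue table
#' @param table a \code{\link{tissueParameterTable}}.
#' @param hct haematocrit (fills the vessel vP).
#' @return data.frame with class_id, name, PS_true, vP_true.
#' @export
tissueTruth <- function(table, hct = 0.45) {
  tab <- as.data.frame(table)
  tab$vP[tab$name == "vessels"] <- 1 - hct
  data.frame(class_id = tab$class_id, name = tab$name,
             PS_true = tab$PS_per_min, vP_true = tab$vP,
             stringsAsFactors = FALSE)
}

#' ROI summary estimates of PS and vP
#'
#' Computes, per tissue class, point estimates of PS and vP by one of four
#' estimators: \code{mean_parameter} / \code{median_parameter} average the
#' voxelwise parametric map within the (optionally eroded) class mask;
#' \code{mean_signal} / \code{median_signal} average the signal time course
#' within the mask first, convert the single ROI curve to concentration
#' using the class T10 and fit it once.
#'
#' @param map a \linkS4class{ParameterMap} (parameter estimators).
#' @param series the acquired \linkS4class{DynamicVolume} (signal
#'   estimators).
#' @param labelMap integer 3D label array at acquired resolution.
#' @param estimator one of "mean_parameter", "median_parameter",
#'   "mean_signal", "median_signal".
#' @param table a \code{\link{tissueParameterTable}} (supplies the class
#'   T10 for signal estimators and the ground truth for error reporting).
#' @param aif,proto needed for the signal estimators.
#' @param erodeRadius spherical erosion radius applied to each class mask
#'   (0 = none).
#' @param classes class IDs to summarise; default = all classes with
#'   Patlak ground truth (brain tissues and vessels).
#' @param excludePost initial post-contrast frames omitted from fitting.
#' @param hct haematocrit.
#' @param t2starCorrection passed to \code{\link{signalToConcentration}}
#'   for the signal estimators.
#' @return data.frame with one row per class: estimates, truth and
#'   relative errors in percent (100 * (est - truth) / truth).
#' @export
summarizeROI <- function(map = NULL, series = NULL, labelMap, estimator,
                         table, aif = NULL, proto = NULL, erodeRadius = 0,
                         classes = NULL, excludePost = 3L, hct = 0.45,
                         t2starCorrection = FALSE) {
  estimator <- match.arg(estimator, c("mean_parameter", "median_parameter",
                                      "mean_signal", "median_signal"))
  truth <- tissueTruth(table, hct)
  if (is.null(classes))
    classes <- table$class_id[table$enhancement_mode == "patlak"]
  classes <- intersect(classes, unique(as.vector(labelMap)))
  rows <- lapply(classes, function(id) {
    m <- labelMap == id
    if (erodeRadius > 0) m <- erodeMask(m, erodeRadius)
    nm <- truth$name[truth$class_id == id]
    if (!any(m)) {
      warning("empty mask after erosion for class ", nm)
      return(data.frame(class_id = id, name = nm, estimator = estimator,
                        eroded = erodeRadius > 0, n_voxels = 0L,
                        PS_est = NA_real_, vP_est = NA_real_))
    }
    if (estimator %in% c("mean_parameter", "median_parameter")) {
      stopifnot(!is.null(map))
      f <- if (estimator == "mean_parameter") mean else stats::median
      ps <- f(psMap(map)[m], na.rm = TRUE)
      vp <- f(vpMap(map)[m], na.rm = TRUE)
    } else {
      stopifnot(!is.null(series), !is.null(aif), !is.null(proto))
      f <- if (estimator == "mean_signal") mean else stats::median
      d <- dim(series@data)
      S <- matrix(series@data, prod(d[1:3]), d[4])
      curve <- apply(S[as.vector(m), , drop = FALSE], 2, f)
      T10 <- table$T10_s[table$class_id == id]
      mini <- DynamicVolume(array(curve, c(1, 1, 1, d[4])),
                            spacing = series@spacing,
                            frameTimes = series@frameTimes)
      C <- signalToConcentration(mini, array(T10, c(1, 1, 1)), proto,
                                 t2starCorrection = t2starCorrection)
      fit <- patlakFit(as.numeric(C), aif, series@frameTimes,
                       nPre = proto@nPre, excludePost = excludePost)
      ps <- fit$PS; vp <- fit$vP
    }
    data.frame(class_id = id, name = nm, estimator = estimator,
               eroded = erodeRadius > 0, n_voxels = sum(m),
               PS_est = ps, vP_est = vp)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, truth, by = c("class_id", "name"), sort = TRUE)
  out$rel_err_PS_pct <- ifelse(out$PS_true != 0,
                               100 * (out$PS_est - out$PS_true) / out$PS_true, NA)
  out$rel_err_vP_pct <- ifelse(out$vP_true != 0,
                               100 * (out$vP_est - out$vP_true) / out$vP_true, NA)
  out[order(out$class_id), ]
}

## ---------------------------------------------------------------------------
## Monte-Carlo harness
## ---------------------------------------------------------------------------

#' Monte-Carlo simulation of repeated DRO measurement
#'
#' Runs \code{nRuns} independent simulate-analyse-summarise passes: each
#' run draws a new starting position, motion trajectory and noise from its
#' own child seed, simulates the acquisition, optionally low-pass filters
#' and realigns, propagates the segmentation, fits the parameter maps and
#' applies the requested estimators with and without mask erosion.
#' Individual run failures are recorded, not fatal.
#'
#' @param vol a \linkS4class{LabelVolume}.
#' @param table a \code{\link{tissueParameterTable}}.
#' @param aif an \linkS4class{AIF}.
#' @param proto an \linkS4class{MRProtocol}.
#' @param nRuns number of runs (the full-scale experiment uses 201; the
#'   packaged demo default is 25).
#' @param seed master seed; every run's randomness derives from it.
#' @param severity motion severity class.
#' @param flags artefact flags, see \code{\link{simulateAcquisition}}.
#' @param realign "oracle", "registration" or "none".
#' @param realignInterp interpolation for realignment resampling.
#' @param segmentation "oracle" or "registration" label propagation.
#' @param estimators subset of the four estimator names.
#' @param erodeRadii vector of erosion radii to evaluate (0 = none).
#' @param lowpassCutoff if not NULL, Bessel low-pass cutoff applied to the
#'   acquired series before analysis.
#' @param excludePost initial post-contrast frames omitted from fitting.
#' @param hct haematocrit.
#' @return tidy data.frame (one row per run x tissue x estimator x
#'   condition) with estimates and relative errors; failed run indices in
#'   attribute \code{"failedRuns"}.
#' @export
runMonteCarlo <- function(vol, table, aif, proto, nRuns = 25L, seed = 1L,
                          severity = "moderate", flags = list(),
                          realign = c("oracle", "registration", "none"),
                          realignInterp = "linear",
                          segmentation = c("oracle", "registration"),
                          estimators = "median_parameter",
                          erodeRadii = 0, lowpassCutoff = NULL,
                          excludePost = 3L, hct = 0.45) {
  realign <- match.arg(realign)
  segmentation <- match.arg(segmentation)
  seeds <- childSeeds(seed, nRuns)
  res <- vector("list", nRuns)
  failed <- integer()
  for (r in seq_len(nRuns)) {
    res[[r]] <- tryCatch({
      acq <- simulateAcquisition(vol, table, aif, proto, severity = severity,
                                 flags = flags, seed = seeds[r])
      if (!is.null(lowpassCutoff))
        acq <- lowpassFilterKspace(acq, cutoff = lowpassCutoff)
      ana <- if (realign == "none") acq
             else realignFrames(acq, mode = realign,
                                interpolation = realignInterp)
      seg <- propagateSegmentation(vol, acq, table = table, aif = aif,
                                   proto = proto, mode = segmentation)
      T10 <- buildT10Map(seg, table)
      pmap <- fitParameterMaps(ana, T10, aif, proto,
                               excludePost = excludePost)
      out <- do.call(rbind, lapply(estimators, function(est)
        do.call(rbind, lapply(erodeRadii, function(er)
          summarizeROI(map = pmap, series = ana, labelMap = seg,
                       estimator = est, table = table, aif = aif,
                       proto = proto, erodeRadius = er,
                       excludePost = excludePost, hct = hct)))))
      out$run <- r
      out
    }, error = function(e) {
      warning("run ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res[[r]])) failed <- c(failed, r)
  }
  out <- do.call(rbind, res)
  attr(out, "failedRuns") <- failed
  attr(out, "seeds") <- seeds
  out
}

#' Aggregate Monte-Carlo results
#'
#' Median and interquartile range of the estimates and of the relative
#' errors across runs, per tissue x estimator x erosion condition.
#' Aggregation is permutation-invariant in run order.
#'
#' @param df output of \code{\link{runMonteCarlo}}.
#' @return data.frame of per-condition summaries.
#' @export
aggregateMonteCarlo <- function(df) {
  key <- interaction(df$class_id, df$estimator, df$eroded, drop = TRUE)
  rows <- lapply(split(df, key), function(g) {
    qPS <- stats::quantile(g$rel_err_PS_pct, c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE)
    qvP <- stats::quantile(g$rel_err_vP_pct, c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE)
    data.frame(class_id = g$class_id[1], name = g$name[1],
               estimator = g$estimator[1], eroded = g$eroded[1],
               n_runs = nrow(g),
               PS_median = stats::median(g$PS_est, na.rm = TRUE),
               vP_median = stats::median(g$vP_est, na.rm = TRUE),
               rel_err_PS_median = qPS[2], rel_err_PS_q1 = qPS[1],
               rel_err_PS_q3 = qPS[3], rel_err_PS_iqr = qPS[3] - qPS[1],
               rel_err_vP_median = qvP[2], rel_err_vP_iqr = qvP[3] - qvP[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$class_id, out$estimator, out$eroded), ]
}
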