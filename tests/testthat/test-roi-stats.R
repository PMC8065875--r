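# Segmentation propagation, T10 maps, erosion, k-space low-pass filter,
# summary estimators and the Monte-Carlo harness.

test_that("spherical erosion obeys the structuring-element arithmetic", {
  m <- array(FALSE, c(9, 9, 9)); m[3:7, 3:7, 3:7] <- TRUE  # solid cube side 5
  e <- erodeMask(m, 1)
  expect_equal(sum(e), 27)                       # cube side 3
  expect_true(all(which(e) %in% which(m)))       # eroded subset of original
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_equal(sum(erodeMask(single, 1)), 0)     # single voxel vanishes
  expect_identical(erodeMask(m, 0), m)
  # boundary voxels erode against the grid edge
  full <- array(TRUE, c(4, 4, 4))
  expect_equal(sum(erodeMask(full, 1)), 8)
})

test_that("segmentation propagation agrees with a nearest-neighbour majority oracle", {
  vol <- fxVol()
  seg <- fxSegIdeal()   # matched grid, no motion: should equal the labels
  expect_equal(mean(seg == labels3D(vol)), 1)

  # coarse grid: compare against block-majority downsampling
  proto <- demoProtocol(fovMM = c(96, 96, 96), acqMatrix = c(32L, 32L, 32L))
  acq <- simulateAcquisition(vol, fxTable(), fxAif(), proto,
                             flags = fxFlagsOff(), seed = 1L)
  seg2 <- propagateSegmentation(vol, acq, mode = "oracle")
  lab <- labels3D(vol)
  oracle <- array(0L, c(32, 32, 32))
  for (i in 1:32) for (j in 1:32) for (k in 1:32) {
    block <- lab[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), (2 * k - 1):(2 * k)]
    tb <- table(block)
    oracle[i, j, k] <- as.integer(names(tb)[which.max(tb)])
  }
  expect_gt(mean(seg2 == oracle), 0.85)
  # every voxel receives exactly one label (an integer array by construction)
  expect_true(is.integer(seg2))
})

test_that("propagated labels follow a known rigid shift of the acquired frame", {
  vol <- fxVol(); proto <- fxProtoIso()
  sh <- RigidTransform(transMM = c(3, -6, 3), centre = c(0, 0, 0)) # integer voxels
  static <- simulateAcquisition(vol, fxTable(), fxAif(), proto,
                                flags = fxFlagsOff(), seed = 1L)
  moved <- simulateAcquisition(vol, fxTable(), fxAif(), proto, start = sh,
    flags = list(startPosition = TRUE, grossMotion = FALSE,
                 motionArtefacts = FALSE, noise = FALSE), seed = 1L)
  s0 <- propagateSegmentation(vol, static, mode = "oracle")
  s1 <- propagateSegmentation(vol, moved, mode = "oracle")
  # one-voxel shift in x, minus two in y, one in z (3 mm voxels)
  shifted <- array(0L, dim(s0))
  shifted[2:32, 1:30, 2:32] <- s0[1:31, 3:32, 1:31]
  inner <- shifted > 0 | s1 > 0
  expect_gt(mean((s1 == shifted)[inner]), 0.97)
})

test_that("regional T10 maps carry the tabulated values", {
  seg <- fxSegIdeal()
  T10 <- buildT10Map(seg, fxTable())
  expect_equal(unique(T10[seg == 2L]), 0.99)   # white matter
  expect_equal(unique(T10[seg == 5L]), 1.34)   # cortical grey matter
  expect_true(all(is.na(T10[seg == 0L])))      # background flagged
  expect_error(buildT10Map(seg, fxTable()[fxTable()$class_id != 2, ]), "2")
})

test_that("Bessel low-pass filter has unit DC gain and mitigates Gibbs ringing", {
  u <- seq(0, 1, by = 0.05)
  H <- besselLowpassResponse(u, order = 4, cutoff = 0.7)
  expect_equal(H[1], 1)
  expect_true(all(diff(H) < 0))                        # monotone low-pass
  expect_equal(besselLowpassResponse(0.7, 4, 0.7), 1 / sqrt(2), tolerance = 1e-3)
  expect_error(besselLowpassResponse(u, cutoff = 1.2), "cutoff")

  # Gibbs test object: a band-limited box whose ringing is fully resolved
  # on its own grid (spectrum of a sharp box truncated to +/- 12 cycles)
  n <- 64L
  x <- numeric(n); x[17:48] <- 1
  K <- stats::fft(x)
  kk <- c(0:(n / 2 - 1), -(n / 2):-1)
  K[abs(kk) > 12] <- 0
  g <- Re(stats::fft(K, inverse = TRUE)) / n
  frame <- array(g, c(n, 8, 8))           # profile varies along x only
  series <- DynamicVolume(array(frame, c(n, 8, 8, 1)),
                          spacing = c(1.5, 12, 12), frameTimes = 0)

  # a flat custom response is the identity
  ident <- lowpassFilterKspace(series, response = function(u) rep(1, length(u)))
  expect_equal(ident@data, series@data, tolerance = 1e-10)

  filt <- lowpassFilterKspace(series, order = 4, cutoff = 0.5)
  # DC preserved: frame mean unchanged within 0.01%
  expect_equal(mean(filt@data), mean(series@data), tolerance = 1e-4)
  # edge overshoot strictly reduced (1-D oracle: the unfiltered profile)
  over <- function(v) max(v) - 1
  expect_gt(over(g), 0.05)
  expect_lt(over(filt@data[, 4, 4, 1]), over(series@data[, 4, 4, 1]))
})

test_that("summary estimators behave as mean/median statistics should", {
  ideal <- fxIdeal(); seg <- fxSegIdeal(); tab <- fxTable()
  proto <- fxProtoMatched(); aif <- fxAif()
  T10 <- buildT10Map(seg, tab)
  pm <- fitParameterMaps(ideal, T10, aif, proto, t2starCorrection = TRUE)

  # in the ideal condition every estimator recovers every tissue within 1%
  for (est in c("mean_parameter", "median_parameter", "mean_signal",
                "median_signal")) {
    s <- summarizeROI(map = pm, series = ideal, labelMap = seg, estimator = est,
                      table = tab, aif = aif, proto = proto,
                      t2starCorrection = TRUE)
    brain <- s[s$PS_true > 0, ]
    expect_lt(max(abs(brain$rel_err_PS_pct)), 1)
    expect_lt(max(abs(s$rel_err_vP_pct)), 1)
  }

  # a single extreme outlier voxel moves the mean but not the median
  pm2 <- pm
  idx <- which(seg == 2L)[1]
  pm2@ps[idx] <- 50   # absurd PS, large enough to drag the ROI mean
  sMean <- summarizeROI(map = pm2, labelMap = seg, estimator = "mean_parameter",
                        table = tab)
  sMed <- summarizeROI(map = pm2, labelMap = seg, estimator = "median_parameter",
                       table = tab)
  base <- summarizeROI(map = pm, labelMap = seg, estimator = "mean_parameter",
                       table = tab)
  expect_gt(sMean$PS_est[sMean$name == "nawm"], 10 * base$PS_est[base$name == "nawm"])
  expect_equal(sMed$PS_est[sMed$name == "nawm"], 2.75e-4, tolerance = 1e-4)

  # homogeneous ROI, noise-free: signal- and parameter-averaging coincide
  sSig <- summarizeROI(map = pm, series = ideal, labelMap = seg,
                       estimator = "mean_signal", table = tab, aif = aif,
                       proto = proto)
  sPar <- summarizeROI(map = pm, labelMap = seg, estimator = "mean_parameter",
                       table = tab)
  expect_equal(sSig$PS_est, sPar$PS_est, tolerance = 0.02)

  # erosion never grows a mask, and summaries of a piecewise-constant ideal
  # map are unchanged by it
  # thin vessel tubes legitimately erode to nothing; that path is flagged
  expect_warning(
    summarizeROI(map = pm, labelMap = seg, estimator = "median_parameter",
                 table = tab, erodeRadius = 1, classes = 13L),
    "empty mask")
  sEro <- suppressWarnings(
    summarizeROI(map = pm, labelMap = seg, estimator = "median_parameter",
                 table = tab, erodeRadius = 1))
  sRaw <- summarizeROI(map = pm, labelMap = seg, estimator = "median_parameter",
                       table = tab)
  expect_true(all(sEro$n_voxels <= sRaw$n_voxels))
  expect_equal(sEro$PS_est[sEro$name == "nawm"],
               sRaw$PS_est[sRaw$name == "nawm"], tolerance = 1e-6)
})

test_that("Monte-Carlo runs are reproducible and differ only through their draws", {
  vol <- fxVol(); tab <- fxTable(); aif <- fxAif()
  proto <- demoProtocol(fovMM = c(96, 96, 96), acqMatrix = c(32L, 32L, 16L))
  args <- list(vol, tab, aif, proto, nRuns = 2L, seed = 77L,
               severity = "none",
               flags = list(grossMotion = FALSE, motionArtefacts = FALSE,
                            noise = FALSE),
               realign = "none", estimators = "median_parameter")
  a <- do.call(runMonteCarlo, args)
  b <- do.call(runMonteCarlo, args)
  expect_equal(a, b)
  # motion and noise off: the two runs differ only via the start position,
  # so their estimates differ but their masks stay plausible
  r1 <- a[a$run == 1 & a$name == "nawm", ]
  r2 <- a[a$run == 2 & a$name == "nawm", ]
  expect_false(isTRUE(all.equal(r1$PS_est, r2$PS_est)))

  # aggregation is permutation-invariant in run order
  sh <- a[rev(seq_len(nrow(a))), ]
  expect_equal(aggregateMonteCarlo(a), aggregateMonteCarlo(sh))
})
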