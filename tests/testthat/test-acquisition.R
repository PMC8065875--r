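# Acquisition simulation: k-space sampling, motion, composite-k-space
# artefacts, noise and reconstruction.

test_that("unitary FFT pair round-trips to machine precision", {
  set.seed(1)
  x <- array(stats::rnorm(16 * 12 * 10), c(16, 12, 10))
  expect_equal(Re(dceDRO:::ifftU(dceDRO:::fftU(x))), x, tolerance = 1e-12)
  expect_equal(sum(Mod(dceDRO:::fftU(x))^2), sum(x^2), tolerance = 1e-12)
})

test_that("random start positions follow the stated uniform law", {
  set.seed(10)
  draws <- t(replicate(10000, {
    tr <- randomStartPosition()
    c(tr@rotDeg, tr@transMM)
  }))
  expect_true(all(abs(draws[, 1:3]) <= 5))
  expect_true(all(abs(draws[, 4:6]) <= 2.5))
  # a 10^4 sample explores the range ends and has near-zero mean
  expect_gt(max(draws[, 1]), 4.8); expect_lt(min(draws[, 1]), -4.8)
  expect_gt(max(draws[, 4]), 2.4); expect_lt(min(draws[, 4]), -2.4)
  expect_lt(max(abs(colMeans(draws[, 1:3]))), 0.15)
  expect_lt(max(abs(colMeans(draws[, 4:6]))), 0.08)
  # degenerate ranges give the identity
  tr0 <- randomStartPosition(0, 0)
  expect_equal(c(tr0@rotDeg, tr0@transMM), rep(0, 6))
  # seeded draws are reproducible
  set.seed(4); a <- randomStartPosition()
  set.seed(4); b <- randomStartPosition()
  expect_equal(a@transMM, b@transMM)
})

test_that("trajectory severities order by mean frame-to-frame brain displacement", {
  set.seed(2)
  pts <- matrix(stats::runif(600, -25, 25), ncol = 3)
  meanDisp <- function(sev) {
    mean(replicate(40, trajectoryDisplacement(
      generateTrajectory(sev, 21), pts)))
  }
  dLow <- meanDisp("low"); dMod <- meanDisp("moderate"); dHigh <- meanDisp("high")
  expect_lt(dLow, 0.5)
  expect_gt(dMod, 0.5); expect_lt(dMod, 1.5)
  expect_gt(dHigh, 1.5)
  none <- generateTrajectory("none", 21)
  expect_true(all(vapply(none@transforms,
                         function(t) all(c(t@rotDeg, t@transMM) == 0),
                         logical(1))))
  set.seed(7); t1 <- generateTrajectory("high", 21)
  set.seed(7); t2 <- generateTrajectory("high", 21)
  expect_equal(t1@transforms[[21]]@transMM, t2@transforms[[21]]@transMM)
})

test_that("rigid resampling honours identities, exact shifts and round trips", {
  set.seed(3)
  arr <- array(stats::rnorm(32^3), c(32, 32, 32))
  A <- dceDRO:::gridAffine(dim(arr), c(2, 2, 2))
  expect_equal(applyRigid(arr, A, RigidTransform()), arr)
  # integer-voxel translation with linear interpolation is an exact shift
  sh <- applyRigid(arr, A, RigidTransform(transMM = c(2, 0, -4)))
  expect_equal(sh[2:32, , 1:30], arr[1:31, , 3:32], tolerance = 1e-12)
  # T then inverse(T) with sinc interpolation restores the interior
  smooth <- Re(dceDRO:::ifftU(dceDRO:::fftU(arr) *
    array(exp(-8 * outer(outer(dceDRO:::freqFraction(32)^2,
                               dceDRO:::freqFraction(32)^2, "+"),
                         dceDRO:::freqFraction(32)^2, "+")), dim(arr))))
  tr <- RigidTransform(rotDeg = c(3, -2, 4), transMM = c(1.2, -0.7, 2.1))
  back <- applyRigid(applyRigid(smooth, A, tr, "sinc"), A, rigidInverse(tr), "sinc")
  core <- 9:24
  rms <- sqrt(mean((back[core, core, core] - smooth[core, core, core])^2))
  expect_lt(rms, 0.01 * diff(range(smooth)))
})

test_that("k-space sampling preserves DC, loses energy only outside the kept block", {
  vol <- fxVol(); proto <- fxProtoDemo()
  f1 <- droFrameFun(vol, fxTable(), fxAif(), proto)(1L)
  K <- sampleKspace(f1, voxelSpacing(vol), proto)
  # DC sample equals the image mean scaled by sqrt(N) of the acquired grid
  expect_equal(Mod(K[1, 1, 1]), mean(f1) * sqrt(prod(proto@acqMatrix)),
               tolerance = 1e-9)
  # Parseval: truncated energy never exceeds the full energy
  scale2 <- prod(proto@acqMatrix) / prod(dim(f1))
  expect_lte(sum(Mod(K)^2) / scale2, sum(Mod(dceDRO:::fftU(f1))^2) * (1 + 1e-12))
  # an acquired matrix larger than the source is rejected
  expect_error(sampleKspace(f1, voxelSpacing(vol),
                            demoProtocol(fovMM = c(96, 96, 96),
                                         acqMatrix = c(128L, 64L, 64L))),
               "exceeds")
  # and so is a mismatched FOV
  expect_error(sampleKspace(f1, voxelSpacing(vol) * 2, proto), "FOV")
})

test_that("truncation of a sharp box produces Gibbs overshoot matching a 1-D oracle", {
  # The box edge sits off-phase with the coarse slice grid (a grid-aligned
  # edge places the acquired samples on the ringing nodes and hides the
  # overshoot; its visibility depends on edge-to-grid phase, which is why
  # the artefact depends on head position).
  n <- 64L
  src <- array(0, c(n, n, n))
  src[17:48, 17:48, 20:51] <- 1
  proto <- demoProtocol(fovMM = c(96, 96, 96), acqMatrix = c(48L, 48L, 12L))
  rec <- Mod(dceDRO:::ifftU(sampleKspace(src, c(1.5, 1.5, 1.5), proto)))

  # 1-D sinc-convolution oracle for one axis: spectrum truncation of the
  # box with the acquired-grid sample positions (self-contained: plain fft
  # index arithmetic, no package helpers)
  oracle1d <- function(m, box, fov = 96, spS = 1.5) {
    x <- numeric(n); x[box] <- 1
    K <- stats::fft(x)
    s <- floor(n / 2)
    Ks <- K[c((n - s + 1):n, 1:(n - s))]              # DC at s + 1
    keep <- Ks[(s + 1 - floor(m / 2)):(s + 1 - floor(m / 2) + m - 1)]
    kk <- seq(-floor(m / 2), length.out = m)          # signed frequencies
    delta <- (fov / m - spS) / 2                      # acquired-grid offset
    keep <- keep * exp(2i * pi * kk * delta / fov)
    un <- keep[c((floor(m / 2) + 1):m, 1:floor(m / 2))]
    Mod(stats::fft(un, inverse = TRUE)) / n
  }
  overshoot <- function(v, inside) max(v) / stats::median(v[inside]) - 1
  gz <- oracle1d(12L, 20:51)
  inside <- 6:8    # acquired slices well inside the box
  ovZ <- overshoot(gz, inside)
  # measured overshoot along the coarsely sampled slice axis, profile
  # through the box centre (the 3-D field is separable for a box, so the
  # normalised profile matches the 1-D oracle)
  profZ <- rec[24, 24, ]
  measured <- overshoot(profZ, inside)
  expect_gt(ovZ, 0.05)               # the oracle predicts visible ringing
  expect_gt(measured, 0.6 * ovZ)
  expect_lt(measured, 1.4 * ovZ)
})

test_that("truncation-only pipeline is linear and preserves a constant object", {
  proto <- demoProtocol(fovMM = c(48, 48, 48), acqMatrix = c(16L, 16L, 16L))
  set.seed(8)
  a <- array(stats::rnorm(32^3), c(32, 32, 32))
  b <- array(stats::rnorm(32^3), c(32, 32, 32))
  ka <- sampleKspace(a, c(1.5, 1.5, 1.5), proto)
  kb <- sampleKspace(b, c(1.5, 1.5, 1.5), proto)
  kab <- sampleKspace(a + b, c(1.5, 1.5, 1.5), proto)
  expect_equal(kab, ka + kb, tolerance = 1e-10)
  # spatially constant object: reconstruction is exact everywhere
  const <- array(7.5, c(32, 32, 32))
  recon <- Mod(dceDRO:::ifftU(sampleKspace(const, c(1.5, 1.5, 1.5), proto)))
  expect_lt(max(abs(recon - 7.5)) / 7.5, 1e-3 * 0.1)
})

test_that("composite k-space mixes the two positions as specified", {
  vol <- fxVol(); proto <- fxProtoDemo()
  f <- droFrameFun(vol, fxTable(), fxAif(), proto)(1L)
  A <- voxelAffine(vol)
  fMoved <- applyRigid(f, A, RigidTransform(transMM = c(6, 3, 0)))
  k1 <- sampleKspace(f, voxelSpacing(vol), proto)
  k2 <- sampleKspace(fMoved, voxelSpacing(vol), proto)
  expect_equal(compositeMotionKspace(k1, k2, 0), k2)
  expect_equal(compositeMotionKspace(k1, k2, 1), k1)
  expect_equal(compositeMotionKspace(k1, k1, 0.47), k1)
  expect_error(compositeMotionKspace(k1, k2[, , 1:8], 0.5), "mismatch")

  # differing positions with a mid split produce ghosting: residual energy
  # outside the object support exceeds the motion-free case
  mix <- compositeMotionKspace(k1, k2, 0.5)
  recMix <- Mod(dceDRO:::ifftU(mix))
  rec1 <- Mod(dceDRO:::ifftU(k1))
  acqA <- dceDRO:::gridAffine(proto@acqMatrix, acquiredSpacing(proto))
  support <- dceDRO:::resampleToGrid((labels3D(vol) > 0) * 1, A,
                                     proto@acqMatrix, acqA) > 0.01
  # evaluate well away from either head position
  bg <- erodeMask(!support, 2)
  expect_gt(sum(recMix[bg]^2), 2 * sum(rec1[bg]^2))
})

test_that("magnitude reconstruction with complex Gaussian noise is Rician", {
  proto <- demoProtocol(fovMM = c(96, 96, 96), acqMatrix = c(32L, 32L, 32L))
  src <- array(0, c(64, 64, 64))
  src[29:36, 29:36, 29:36] <- 400
  k <- sampleKspace(src, c(1.5, 1.5, 1.5), proto)
  expect_equal(addNoiseAndReconstruct(k, 0), Mod(dceDRO:::ifftU(k)))
  # an empty scene isolates the background law: all voxels have true
  # signal 0 and must follow a Rayleigh distribution of scale sigma
  sigma <- 5
  set.seed(21)
  bg <- as.vector(addNoiseAndReconstruct(k * 0, sigma))  # 32^3 > 10^4 voxels
  expect_gt(length(bg), 1e4)
  # Rayleigh law: mean/sd = sqrt(pi/2) / sqrt(2 - pi/2) = 1.9131
  expect_equal(mean(bg) / stats::sd(bg), 1.9131, tolerance = 0.03)
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.03)
  expect_error(addNoiseAndReconstruct(k, -1))
})

test_that("acquisition simulation is seed-reproducible and honours its flags", {
  vol <- fxVol(); tab <- fxTable(); aif <- fxAif(); proto <- fxProtoDemo()
  a <- simulateAcquisition(vol, tab, aif, proto, severity = "moderate", seed = 31L)
  b <- simulateAcquisition(vol, tab, aif, proto, severity = "moderate", seed = 31L)
  expect_identical(a@data, b@data)
  c <- simulateAcquisition(vol, tab, aif, proto, severity = "moderate", seed = 32L)
  expect_false(identical(a@data, c@data))

  # truncation-only static series on a matched grid reproduces the source
  ideal <- fxIdeal()
  dro <- droFrameFun(vol, tab, aif, fxProtoMatched())
  for (t in c(1L, 12L))
    expect_equal(getFrame(ideal, t), dro(t), tolerance = 1e-8)
})
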