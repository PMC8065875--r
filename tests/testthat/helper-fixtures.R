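# Shared fixtures, built once per session and cached. All tests work on a
# desk-scale head: 64^3 voxels at 1.5 mm (96 mm FOV) unless stated.

.fx <- new.env(parent = emptyenv())

fxMemo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fxSpec <- function() phantomSpec(dim = c(64L, 64L, 64L),
                                 spacingMM = c(1.5, 1.5, 1.5))

fxVol <- function() fxMemo("vol", buildSyntheticHead(fxSpec(), seed = 2L))

fxTable <- function() fxMemo("table", defaultTissueTable())

fxAif <- function() defaultAIF(onsetS = 73)

# demo-proportioned acquired grid (in-plane fine, slice coarse)
fxProtoDemo <- function() demoProtocol(fovMM = c(96, 96, 96),
                                       acqMatrix = c(48L, 40L, 16L))

# acquired grid matched to the source grid (no truncation)
fxProtoMatched <- function() demoProtocol(fovMM = c(96, 96, 96),
                                          acqMatrix = c(64L, 64L, 64L))

# isotropic acquired grid used by the registration-accuracy checks
fxProtoIso <- function() demoProtocol(fovMM = c(96, 96, 96),
                                      acqMatrix = c(32L, 32L, 32L))

fxFlagsOff <- function() list(startPosition = FALSE, grossMotion = FALSE,
                              motionArtefacts = FALSE, noise = FALSE)

# truncation-only static acquisition on the demo grid
fxStaticDemo <- function() fxMemo("staticDemo",
  simulateAcquisition(fxVol(), fxTable(), fxAif(), fxProtoDemo(),
                      flags = fxFlagsOff(), seed = 1L))

# ideal acquisition: matched grid, static, noise-free
fxIdeal <- function() fxMemo("ideal",
  simulateAcquisition(fxVol(), fxTable(), fxAif(), fxProtoMatched(),
                      flags = fxFlagsOff(), seed = 1L))

fxSegIdeal <- function() fxMemo("segIdeal",
  propagateSegmentation(fxVol(), fxIdeal(), mode = "oracle"))

# residual mean displacement (mm) between an estimated transform and the
# inverse of the true one, over a brain-sized point cloud
residualDisplacement <- function(est, truth) {
  set.seed(99)
  pts <- matrix(stats::runif(300, -25, 25), ncol = 3)
  dceDRO:::meanPointDisplacement(pts, diag(4),
                                 rigidMatrix(rigidCompose(est, truth)))
}
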