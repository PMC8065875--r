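## Internal geometry, FFT and quadrature helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default voxel-to-world affine for a centred grid
#'
#' Builds the 4x4 affine mapping 0-based voxel indices to RAS world
#' coordinates (mm) for an axis-aligned grid whose centre sits at the world
#' origin. All volumes produced by the package use this convention unless an
#' affine is read from file.
#'
#' @param dim integer(3) grid size in voxels.
#' @param spacing numeric(3) voxel size in mm.
#' @return 4x4 numeric matrix.
#' @keywords internal
gridAffine <- function(dim, spacing) {
  stopifnot(length(dim) == 3L, length(spacing) == 3L, all(spacing > 0))
  A <- diag(4)
  diag(A)[1:3] <- spacing
  A[1:3, 4] <- -spacing * (dim - 1) / 2
  A
}

## world coordinates (mm) of every voxel along one axis, 0-based index i
axisWorld <- function(dim, affine, axis) {
  idx <- seq_len(dim[axis]) - 1
  affine[axis, axis] * idx + affine[axis, 4]
}

## Unitary n-dimensional FFT pair: both directions scale by 1/sqrt(N) so
## white noise of sd sigma maps to white noise of sd sigma in either domain.
fftU <- function(x) stats::fft(x) / sqrt(length(x))

ifftU <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

## Permutation placing the DC sample (unshifted index 1) at floor(n/2)+1.
fftshiftIdx <- function(n) {
  s <- floor(n / 2)
  c((n - s + 1):n, 1:(n - s))
}

ifftshiftIdx <- function(n) {
  s <- ceiling(n / 2)
  c((n - s + 1):n, 1:(n - s))
}

fftshift3 <- function(x) {
  d <- dim(x)
  x[fftshiftIdx(d[1]), fftshiftIdx(d[2]), fftshiftIdx(d[3]), drop = FALSE]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  x[ifftshiftIdx(d[1]), ifftshiftIdx(d[2]), ifftshiftIdx(d[3]), drop = FALSE]
}

## Central block extraction in k-space, DC kept at the centre index
## floor(N/2)+1 of the shifted layout (even/odd lengths handled by this one
## convention). Returns an unshifted array of size outDim.
cropKspaceCentred <- function(K, outDim) {
  d <- dim(K)
  stopifnot(all(outDim <= d), all(outDim >= 1))
  Ks <- fftshift3(K)
  sel <- lapply(1:3, function(a) {
    cN <- floor(d[a] / 2) + 1
    (cN - floor(outDim[a] / 2)):(cN - floor(outDim[a] / 2) + outDim[a] - 1)
  })
  ifftshift3(Ks[sel[[1]], sel[[2]], sel[[3]], drop = FALSE])
}

## Normalised frequency per unshifted index, as a fraction of Nyquist.
freqFraction <- function(n) {
  f <- c(0:(ceiling(n / 2) - 1), -(n - ceiling(n / 2)):-1)
  f / (n / 2)
}

## Cumulative trapezoidal integral of y over x (same length), starting at 0.
cumtrapz <- function(y, x) {
  n <- length(y)
  stopifnot(length(x) == n)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Deterministic child seeds from one master seed
#'
#' Derives a reproducible vector of independent seeds, used so that every
#' stage and every Monte-Carlo run of an experiment draws from its own
#' stream while remaining fully determined by a single master seed.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length \code{n}, each in \code{[1, 2^31-2]}.
#' @export
childSeeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(2147483646L, n)
}

## Mean Euclidean displacement (mm) of a point cloud under the world map
## moving from transform A to transform B.
meanPointDisplacement <- function(pts, matA, matB) {
  P <- rbind(t(pts), 1)
  mean(sqrt(colSums(((matB %*% P) - (matA %*% P))[1:3, , drop = FALSE]^2)))
}
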