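# 3D reconstruction by direct Fourier inversion (central-slice gridding
# with per-voxel weight normalisation), C7 symmetrisation, split-half FSC
# resolution estimation and the final amplitude filter.
#
# Side-view-only data leave a polar cone of Fourier space unmeasured;
# those voxels are left at zero (the experimental missing-cone
# constraint) and flagged in the return attributes.

#' Reconstruct a 3D map from oriented particle images
#'
#' Direct Fourier inversion: each image's 2D DFT is inserted as a central
#' slice at its ZYZ orientation (with the recorded shifts removed by
#' phase correction), accumulated with trilinear gridding weights,
#' normalised per voxel and inverted.  With `imposeSymmetry` the map is
#' C-n symmetrised about z by real-space averaging of the n rotated
#' copies.  The operation is linear in the input images.
#'
#' @param images N x N x P array (or a [ParticleStack-class]).
#' @param eulerDeg P x 3 matrix of phi, theta, psi (degrees).
#' @param shiftsPx P x 2 applied shifts in pixels (removed here).
#' @param voxelA voxel size (pixel size of the images).
#' @param imposeSymmetry symmetrise about z (FALSE reproduces the
#'   asymmetric-refinement check).
#' @param nFoldSym symmetry order.
#' @return A [DensityMap-class]; attribute `unmeasured_fraction` gives the
#'   fraction of in-band Fourier voxels with no data.
#' @export
reconstructC7 <- function(images, eulerDeg, shiftsPx = NULL, voxelA = NULL,
                          imposeSymmetry = TRUE, nFoldSym = 7) {
  if (is(images, "ParticleStack")) {
    if (is.null(voxelA)) voxelA <- images@pixelA
    images <- particleImages(images)
  }
  if (is.null(voxelA)) stop("voxelA required")
  N <- dim(images)[1]
  P <- dim(images)[3]
  eulerDeg <- matrix(eulerDeg, ncol = 3)
  if (is.null(shiftsPx)) shiftsPx <- matrix(0, P, 2)
  shiftsPx <- matrix(shiftsPx, ncol = 2)
  if (P < 2 * nFoldSym)
    warning("fewer than ", 2 * nFoldSym, " particles: under-determined reconstruction")
  fstack <- array(0i, dim(images))
  for (p in seq_len(P)) fstack[, , p] <- fft(images[, , p])
  rot <- array(0, c(3, 3, P))
  for (p in seq_len(P)) rot[, , p] <- eulerMatrix(eulerDeg[p, ])
  ins <- cpp_fourier_insert(fstack, rot, shiftsPx)
  wt <- ins$wt
  Fv <- ins$num
  measured <- wt > 1e-8
  Fv[measured] <- Fv[measured] / wt[measured]
  Fv[!measured] <- 0
  # undo the centre-phase checkerboard and invert
  h <- (-1)^(seq_len(N) - 1)
  chk <- array(outer(outer(h, h), h), c(N, N, N))
  vol <- Re(fft(Fv * chk, inverse = TRUE)) / N^3
  if (imposeSymmetry) vol <- cpp_symmetrize_z(vol, as.integer(nFoldSym))
  # fraction of the in-band sphere left unmeasured (missing cone etc.)
  fr <- radialFreqGrid3D(N, 1)
  inband <- fr <= 0.5 - 1 / N
  out <- DensityMap(vol, voxelA)
  attr(out, "unmeasured_fraction") <- sum(!measured & inband) / sum(inband)
  out
}

# |frequency| grid in 1/(unit * N) terms for cubic N^3
radialFreqGrid3D <- function(N, pixelA) {
  h <- fftFreqIndex(N) / (N * pixelA)
  a1 <- array(rep(h, times = N * N), c(N, N, N))
  a2 <- array(rep(rep(h, each = N), times = N), c(N, N, N))
  a3 <- array(rep(h, each = N * N), c(N, N, N))
  sqrt(a1^2 + a2^2 + a3^2)
}

#' Soft-edged spherical mask
#'
#' @param N box side in voxels.
#' @param radiusFrac mask radius as a fraction of the box width.
#' @param edgeVox raised-cosine edge width in voxels.
#' @return N^3 array in `[0, 1]`.
#' @export
softSphereMask <- function(N, radiusFrac = 0.45, edgeVox = 5) {
  x <- seq_len(N) - 1 - N / 2
  r <- sqrt(outer(outer(x^2, x^2, `+`), x^2, `+`))
  r0 <- radiusFrac * N
  m <- ifelse(r <= r0, 1,
              ifelse(r >= r0 + edgeVox, 0,
                     0.5 * (1 + cos(pi * (r - r0) / edgeVox))))
  array(m, c(N, N, N))
}

#' Fourier shell correlation between two maps
#'
#' Shell-wise normalised cross-correlation of the Fourier coefficients,
#' shells one Fourier voxel wide.
#'
#' @param mapA,mapB [DensityMap-class] objects (or arrays) on the same
#'   grid.
#' @param voxelA voxel size if arrays are passed.
#' @param threshold resolution criterion carried on the curve (0.5).
#' @return An [FSCCurve-class].
#' @export
fscCurve <- function(mapA, mapB, voxelA = NULL, threshold = 0.5) {
  if (is(mapA, "DensityMap")) { voxelA <- voxelSize(mapA); mapA <- mapGrid(mapA) }
  if (is(mapB, "DensityMap")) mapB <- mapGrid(mapB)
  if (is.null(voxelA)) stop("voxelA required for bare arrays")
  N <- dim(mapA)[1]
  FA <- fft(mapA)
  FB <- fft(mapB)
  shell <- round(radialFreqGrid3D(N, 1) * N)   # integer shell index
  maxS <- N %/% 2 - 1
  keep <- shell <= maxS & shell >= 1
  num <- Re(tapply(Re(FA * Conj(FB))[keep], shell[keep], sum))
  da <- tapply(abs(FA[keep])^2, shell[keep], sum)
  db <- tapply(abs(FB[keep])^2, shell[keep], sum)
  corr <- as.numeric(num / sqrt(da * db))
  corr[!is.finite(corr)] <- 0
  freq <- as.integer(names(num)) / (N * voxelA)
  new("FSCCurve", shellFreq = freq, correlation = corr, threshold = threshold)
}

#' Split-half FSC from an oriented stack
#'
#' Even/odd split, two independent reconstructions, soft-edged spherical
#' masking, then shell-wise FSC.
#'
#' @inheritParams reconstructC7
#' @param mask apply the soft spherical mask before correlating.
#' @param maskRadiusFrac,edgeVox mask geometry.
#' @return An [FSCCurve-class].
#' @export
splitHalfFSC <- function(images, eulerDeg, shiftsPx = NULL, voxelA = NULL,
                         imposeSymmetry = TRUE, nFoldSym = 7, mask = TRUE,
                         maskRadiusFrac = 0.45, edgeVox = 5) {
  if (is(images, "ParticleStack")) {
    if (is.null(voxelA)) voxelA <- images@pixelA
    images <- particleImages(images)
  }
  P <- dim(images)[3]
  if (P < 4) stop("need at least 2 particles per half")
  eulerDeg <- matrix(eulerDeg, ncol = 3)
  if (is.null(shiftsPx)) shiftsPx <- matrix(0, P, 2)
  shiftsPx <- matrix(shiftsPx, ncol = 2)
  idx <- list(seq(1, P, 2), seq(2, P, 2))
  halves <- lapply(idx, function(i)
    mapGrid(reconstructC7(images[, , i, drop = FALSE],
                          eulerDeg[i, , drop = FALSE],
                          shiftsPx[i, , drop = FALSE], voxelA,
                          imposeSymmetry, nFoldSym)))
  if (mask) {
    m <- softSphereMask(dim(halves[[1]])[1], maskRadiusFrac, edgeVox)
    halves <- lapply(halves, function(v) v * m)
  }
  fscCurve(halves[[1]], halves[[2]], voxelA = voxelA)
}

#' Resolution at an FSC threshold
#'
#' The first frequency where the curve crosses the threshold, linearly
#' interpolated between shells, returned in Angstrom.  If the curve never
#' drops below the threshold the band limit (2 voxels) is returned.
#'
#' @param curve an [FSCCurve-class].
#' @param threshold overrides the curve's stored criterion.
#' @return resolution in Angstrom.
#' @export
resolutionAtThreshold <- function(curve, threshold = curve@threshold) {
  f <- curve@shellFreq
  c_ <- curve@correlation
  below <- which(c_ < threshold)
  if (length(below) == 0) return(1 / max(f))
  i <- below[1]
  if (i == 1) return(1 / f[1])
  # linear interpolation between shells i-1 and i
  f0 <- f[i - 1] + (f[i] - f[i - 1]) *
    (c_[i - 1] - threshold) / (c_[i - 1] - c_[i])
  1 / f0
}

#' Final amplitude filter
#'
#' The band filter applied to finished reconstructions: amplitudes below
#' `1/lowA` are multiplied by `lowFreqFactor` (0.1: low frequencies
#' reduced to 10% to correct their over-representation), the band interior
#' is unchanged, and a raised-cosine roll-off removes frequencies beyond
#' `1/highA`.  With `lowFreqFactor = 1` and `highA` at Nyquist the filter
#' is the identity.
#'
#' @param map a [DensityMap-class].
#' @param lowA,highA band edges in Angstrom (20 and 8.5 in the standard
#'   protocol).
#' @param lowFreqFactor multiplier for amplitudes below `1/lowA`.
#' @param edgePx raised-cosine edge width in Fourier pixels.
#' @return filtered [DensityMap-class].
#' @export
finalFilter <- function(map, lowA = 20, highA = 8.5, lowFreqFactor = 0.1,
                        edgePx = 2) {
  v <- mapGrid(map)
  px <- voxelSize(map)
  N <- dim(v)[1]
  if (is.finite(highA) && highA < 2 * px - 1e-9)
    stop("highA cutoff beyond Nyquist")
  fr <- radialFreqGrid3D(N, px)
  df <- 1 / (N * px)
  w <- edgePx * df / 2
  flo <- 1 / lowA
  g <- ifelse(fr <= flo - w, lowFreqFactor,
              ifelse(fr >= flo + w, 1,
                     lowFreqFactor + (1 - lowFreqFactor) *
                       0.5 * (1 - cos(pi * (fr - flo + w) / (2 * w)))))
  if (highA > 2 * px + 1e-9) {
    fhi <- 1 / highA
    g <- g * ifelse(fr <= fhi, 1,
                    ifelse(fr >= fhi + 2 * w, 0,
                           0.5 * (1 + cos(pi * (fr - fhi) / (2 * w)))))
  }
  out <- Re(fft(fft(v) * g, inverse = TRUE)) / N^3
  DensityMap(out, px, map@originA)
}
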