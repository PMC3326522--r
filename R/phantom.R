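# Density synthesis, projection and particle simulation from phantom
# models.  The same Gaussian pseudo-atom kernel is used here and by the
# fitting module's cross-correlation scoring, so model and map are always
# rendered identically.

# Gaussian width for a nominal resolution: the kernel's Fourier amplitude
# falls to 1/e at 1/resolution.
sigmaForResolution <- function(resolutionA) resolutionA / (pi * sqrt(2))

#' Render a density map from pseudo-atom coordinates
#'
#' Sum of isotropic Gaussians centred on the atoms, width set so the
#' Fourier amplitude falls to 1/e at `1/resolutionA`; each atom's discrete
#' kernel is normalised so the integrated density (`sum(grid)`) equals the
#' total mass weight exactly.
#'
#' @param coords n x 3 matrix, Angstrom; the grid centre is at (0,0,0).
#' @param mass atom mass weights (recycled).
#' @param voxelA voxel size in Angstrom.
#' @param boxVox box side in voxels.
#' @param resolutionA nominal resolution; must be at least `2*voxelA`.
#' @return A [DensityMap-class].
#' @export
densityFromCoords <- function(coords, mass = 1, voxelA, boxVox,
                              resolutionA = 8) {
  if (resolutionA < 2 * voxelA - 1e-9)
    stop("sub-Nyquist resolution request: resolutionA must be >= 2*voxelA")
  half <- boxVox * voxelA / 2
  if (max(abs(coords)) * 1.1 > half)
    stop("model (plus 10% margin) extends beyond the box")
  mass <- rep_len(mass, nrow(coords))
  grid_xyz <- coords / voxelA + boxVox / 2
  g <- cpp_synth_density(grid_xyz, mass, as.integer(boxVox),
                         sigmaForResolution(resolutionA) / voxelA)
  DensityMap(g, voxelA)
}

#' Render a phantom model into a density map
#'
#' @param model a [PhantomModel-class].
#' @inheritParams densityFromCoords
#' @return A [DensityMap-class].
#' @examples
#' m <- buildStateModel("T", "T")
#' v <- synthesizeDensity(m, voxelA = 4, boxVox = 64, resolutionA = 8)
#' @export
synthesizeDensity <- function(model, voxelA = 4, boxVox = 64,
                              resolutionA = 8) {
  densityFromCoords(atomCoords(model), model@atoms$mass, voxelA, boxVox,
                    resolutionA)
}

#' Project a density map along a viewing direction
#'
#' Line integral of the density along the rotated z axis, ZYZ intrinsic
#' Euler angles in degrees (the final Z is the in-plane rotation).  Energy
#' is conserved: `sum(projection) = sum(map) * voxelA` up to interpolation
#' error.
#'
#' @param map a [DensityMap-class].
#' @param eulerDeg numeric(3): phi, theta, psi in degrees.
#' @return N x N numeric matrix (projected density x Angstrom).
#' @export
projectMap <- function(map, eulerDeg) {
  cpp_project(mapGrid(map), eulerMatrix(eulerDeg)) * voxelSize(map)
}

#' Simulate a particle stack from a mixture of conformers
#'
#' Emulates a side-view data set: for each particle the state is drawn
#' from the model list, the out-of-plane tilt is uniform in
#' `tiltRangeDeg`, azimuth and in-plane rotation are uniform over the full
#' circle, sub-pixel shifts are uniform within `shiftMaxPx`, defocus is
#' uniform in `defocusRangeUm`; the CTF is applied in Fourier space and
#' white Gaussian noise is added to the requested signal-to-noise ratio
#' (signal variance over noise variance inside the particle-radius mask).
#' All ground truth is recorded in the metadata.
#'
#' @param models named list of [PhantomModel-class] objects, or a character
#'   vector of canonical state names (each built on a T bottom ring, except
#'   Rd states which get matching double-ATP rings).
#' @param nPerModel particles per model.
#' @param snr signal-to-noise ratio; `Inf` for noise-free.
#' @param seed integer seed (required; the stack is bit-reproducible).
#' @param voxelA,boxVox,resolutionA rendering geometry.
#' @param tiltRangeDeg out-of-plane tilt range (degrees to the symmetry
#'   axis; side views are 80-100).
#' @param shiftMaxPx maximum |shift| per axis in pixels (0 disables).
#' @param defocusRangeUm underfocus range in micrometres.
#' @param ctf CTF parameter template from [ctfParams()] (defocus is
#'   overridden per particle); `NULL` disables CTF modulation.
#' @param maskRadiusFrac particle-radius mask for the SNR normalisation,
#'   as a fraction of the box width.
#' @return A [ParticleStack-class] with ground-truth metadata.
#' @export
simulateStack <- function(models, nPerModel = 100, snr = 0.1, seed,
                          voxelA = 4, boxVox = 64, resolutionA = 8,
                          tiltRangeDeg = c(80, 100), shiftMaxPx = 3,
                          defocusRangeUm = c(0.7, 3.5),
                          ctf = ctfParams(defocusUm = 2, pixelA = voxelA),
                          maskRadiusFrac = 0.4) {
  if (missing(seed)) stop("a seed is required")
  if (is.character(models)) {
    nm <- models
    models <- lapply(nm, function(s)
      buildStateModel(s, if (startsWith(s, "Rd")) s else "T"))
    names(models) <- nm
  }
  if (length(models) == 0) stop("empty model list")
  if (nPerModel <= 0) stop("nPerModel must be positive")
  if (is.null(names(models)))
    names(models) <- paste0("state", seq_along(models))
  set.seed(seed)
  vols <- lapply(models, function(m)
    mapGrid(synthesizeDensity(m, voxelA, boxVox, resolutionA)))
  N <- boxVox
  P <- nPerModel * length(models)
  state <- rep(names(models), each = nPerModel)
  meta <- data.frame(
    index = seq_len(P), state = state,
    phi = runif(P, 0, 360), theta = runif(P, tiltRangeDeg[1], tiltRangeDeg[2]),
    psi = runif(P, 0, 360),
    sx = if (shiftMaxPx > 0) runif(P, -shiftMaxPx, shiftMaxPx) else rep(0, P),
    sy = if (shiftMaxPx > 0) runif(P, -shiftMaxPx, shiftMaxPx) else rep(0, P),
    defocus_um = runif(P, defocusRangeUm[1], defocusRangeUm[2]),
    seed = seed, stringsAsFactors = FALSE)
  mask <- radialMask2D(N) <= maskRadiusFrac * N
  imgs <- array(0, c(N, N, P))
  for (p in seq_len(P)) {
    proj <- cpp_project(vols[[meta$state[p]]],
                        eulerMatrix(c(meta$phi[p], meta$theta[p], meta$psi[p]))) * voxelA
    cpar <- ctf
    if (!is.null(cpar)) cpar$defocusUm <- meta$defocus_um[p]
    img <- ctfShiftApply(proj, cpar, c(meta$sx[p], meta$sy[p]), voxelA)
    if (is.finite(snr)) {
      vs <- var(img[mask])
      img <- img + rnorm(N * N, sd = sqrt(vs / snr))
    }
    imgs[, , p] <- img
  }
  ParticleStack(imgs, pixelA = voxelA, meta = meta)
}

# apply CTF modulation and a (sub-pixel) translation in Fourier space
ctfShiftApply <- function(img, ctf, shiftPx, pixelA) {
  N <- nrow(img)
  FT <- fft(img)
  if (!is.null(ctf)) {
    fr <- radialFreqGrid2D(N, pixelA)
    FT <- FT * ctfEvaluate(ctf, fr)
  }
  if (any(shiftPx != 0)) {
    h <- fftFreqIndex(N)
    ph <- outer(h * shiftPx[1], h * shiftPx[2], `+`) * (2 * pi / N)
    FT <- FT * exp(-1i * ph)
  }
  Re(fft(FT, inverse = TRUE)) / (N * N)
}

# integer DFT frequency index per axis position
fftFreqIndex <- function(N) {
  h <- seq_len(N) - 1
  ifelse(h <= N / 2, h, h - N)
}

# |frequency| grid in 1/Angstrom for an N x N image
radialFreqGrid2D <- function(N, pixelA) {
  h <- fftFreqIndex(N) / (N * pixelA)
  sqrt(outer(h^2, h^2, `+`))
}

# radial pixel distance from the grid centre (0-based index N/2)
radialMask2D <- function(N) {
  x <- seq_len(N) - 1 - N / 2
  sqrt(outer(x^2, x^2, `+`))
}

#' Angular sampling of the side-view asymmetric unit
#'
#' The azimuthal asymmetric unit of a C-n-symmetric particle spans 360/n
#' degrees (51.4 for C7); side views cover tilts of 80-100 degrees to the
#' symmetry axis.
#'
#' @param nFoldSym symmetry order.
#' @param aziStepDeg azimuth step (the final alignment protocol uses 1).
#' @param tiltSetDeg tilt values to sample.
#' @return list: `extent_deg` (= 360/n), `grid` (data.frame phi, theta).
#' @export
angularGrid <- function(nFoldSym = 7, aziStepDeg = 1,
                        tiltSetDeg = c(80, 85, 90, 95, 100)) {
  extent <- 360 / nFoldSym
  phi <- seq(0, extent - 1e-9, by = aziStepDeg)
  list(extent_deg = extent,
       grid = expand.grid(phi = phi, theta = tiltSetDeg))
}
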