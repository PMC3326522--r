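# Image-level preprocessing: weak-phase CTF model, phase-flip
# correction, binning, box handling, band-pass filtering and
# normalisation.  All cutoffs are given in Angstrom and converted via the
# pixel size; filter edges are raised-cosine ramps two Fourier pixels
# wide.

#' CTF parameters
#'
#' Standard weak-phase contrast transfer model.  Underfocus is positive;
#' the defaults match a 120 kV side-entry instrument with images binned to
#' 2.02 Angstrom per pixel.
#'
#' @param defocusUm underfocus in micrometres, in (0, 10].
#' @param voltageKv acceleration voltage in kV.
#' @param csMm spherical aberration in mm.
#' @param amplitudeContrast amplitude contrast fraction in `[0, 0.3]`.
#' @param pixelA pixel size in Angstrom.
#' @return list of CTF parameters.
#' @export
ctfParams <- function(defocusUm = 2, voltageKv = 120, csMm = 2,
                      amplitudeContrast = 0.07, pixelA = 2.02) {
  if (defocusUm <= 0 || defocusUm > 10)
    stop("defocusUm must be in (0, 10]")
  if (amplitudeContrast < 0 || amplitudeContrast > 0.3)
    stop("amplitudeContrast must be in [0, 0.3]")
  list(defocusUm = defocusUm, voltageKv = voltageKv, csMm = csMm,
       amplitudeContrast = amplitudeContrast, pixelA = pixelA)
}

# relativistic electron wavelength in Angstrom
electronWavelengthA <- function(voltageKv) {
  V <- voltageKv * 1000
  12.2639 / sqrt(V * (1 + 0.97845e-6 * V))
}

#' Evaluate the contrast transfer function
#'
#' `CTF(f) = -(sqrt(1-A^2) sin(chi) + A cos(chi))` with phase aberration
#' `chi(f) = pi lambda dz f^2 - (pi/2) Cs lambda^3 f^4`; at zero frequency
#' the value is `-A` (pure amplitude contrast).
#'
#' @param params from [ctfParams()].
#' @param spatialFreq frequency (1/Angstrom), scalar, vector or matrix.
#' @return contrast values in `[-1, 1]`, same shape as `spatialFreq`.
#' @export
ctfEvaluate <- function(params, spatialFreq) {
  lam <- electronWavelengthA(params$voltageKv)
  dz <- params$defocusUm * 1e4          # um -> A
  cs <- params$csMm * 1e7               # mm -> A
  f2 <- spatialFreq^2
  chi <- pi * lam * dz * f2 - (pi / 2) * cs * lam^3 * f2^2
  A <- params$amplitudeContrast
  -(sqrt(1 - A^2) * sin(chi) + A * cos(chi))
}

#' CTF correction by phase flipping
#'
#' Multiplies every Fourier coefficient by the sign of the CTF at its
#' radial frequency; an involution (applying it twice restores the input)
#' and the standard minimal CTF correction.
#'
#' @param image square image matrix.
#' @param params from [ctfParams()] (pixel size taken from there unless
#'   given).
#' @param pixelA overrides the parameter set's pixel size.
#' @return corrected image.
#' @export
phaseFlip <- function(image, params, pixelA = params$pixelA) {
  if (nrow(image) != ncol(image)) stop("image must be square")
  N <- nrow(image)
  s <- sign(ctfEvaluate(params, radialFreqGrid2D(N, pixelA)))
  s[s == 0] <- 1
  Re(fft(fft(image) * s, inverse = TRUE)) / (N * N)
}

#' 2x2 binning
#'
#' Averages 2x2 pixel blocks, halving the image and doubling the pixel
#' size.
#'
#' @param image matrix with even dimensions.
#' @return binned matrix.
#' @export
bin2x2 <- function(image) {
  d <- dim(image)
  if (any(d %% 2 != 0)) stop("dimensions must be even for 2x2 binning")
  (image[seq(1, d[1], 2), seq(2, d[2], 2)] +
     image[seq(2, d[1], 2), seq(2, d[2], 2)] +
     image[seq(1, d[1], 2), seq(1, d[2], 2)] +
     image[seq(2, d[1], 2), seq(1, d[2], 2)]) / 4
}

#' Extract a square box around a centre
#'
#' @param image source matrix.
#' @param center numeric(2), 1-based pixel coordinates.
#' @param size box side in pixels.
#' @return `size` x `size` matrix (zero-padded at the image edge).
#' @export
extractBox <- function(image, center, size = 256) {
  out <- matrix(0, size, size)
  i0 <- round(center[1]) - size %/% 2
  j0 <- round(center[2]) - size %/% 2
  ii <- seq_len(size) + i0 - 1
  jj <- seq_len(size) + j0 - 1
  ok_i <- ii >= 1 & ii <= nrow(image)
  ok_j <- jj >= 1 & jj <= ncol(image)
  out[ok_i, ok_j] <- image[ii[ok_i], jj[ok_j]]
  out
}

#' Crop a box to a smaller centred window
#'
#' @param image square matrix.
#' @param size target side (e.g. 256 -> 192).
#' @return cropped matrix.
#' @export
cropBox <- function(image, size = 192) {
  N <- nrow(image)
  if (size > N) stop("crop size exceeds the box")
  o <- (N - size) %/% 2
  image[o + seq_len(size), o + seq_len(size)]
}

# raised-cosine band-pass gain profile over |f|; edge width in Fourier px
bandGain <- function(fr, N, pixelA, lowA, highA, edgePx = 2) {
  df <- 1 / (N * pixelA)
  w <- edgePx * df / 2
  g <- rep(1, length(fr))
  if (is.finite(lowA) && lowA > 0) {
    flo <- 1 / lowA
    g <- g * ifelse(fr <= flo - w, 0,
                    ifelse(fr >= flo + w, 1,
                           0.5 * (1 - cos(pi * (fr - flo + w) / (2 * w)))))
  }
  if (is.finite(highA) && highA > 2 * pixelA + 1e-9) {
    fhi <- 1 / highA
    g <- g * ifelse(fr <= fhi - w, 1,
                    ifelse(fr >= fhi + w, 0,
                           0.5 * (1 + cos(pi * (fr - fhi + w) / (2 * w)))))
  }
  g
}

#' Band-pass filter and normalise a particle image
#'
#' Soft-edged (raised cosine, two Fourier pixels wide) annular band-pass
#' between `lowA` and `highA`, followed by normalisation to zero mean and
#' unit variance measured outside the particle-radius mask (the
#' background).  The DC component is removed.
#'
#' @param image square matrix.
#' @param lowA long-wavelength cutoff in Angstrom (175 in the standard
#'   protocol).
#' @param highA short-wavelength cutoff in Angstrom.
#' @param pixelA pixel size.
#' @param maskRadiusFrac particle mask radius as a fraction of box width.
#' @return filtered, background-normalised image.
#' @export
bandpassNormalize <- function(image, lowA = 175, highA = 4, pixelA,
                              maskRadiusFrac = 0.4) {
  N <- nrow(image)
  if (is.finite(highA) && highA < 2 * pixelA - 1e-9)
    stop("highA cutoff beyond Nyquist")
  fr <- radialFreqGrid2D(N, pixelA)
  g <- matrix(bandGain(fr, N, pixelA, lowA, highA), N, N)
  g[1, 1] <- 0
  out <- Re(fft(fft(image) * g, inverse = TRUE)) / (N * N)
  # the DC term is already zero, so the global mean is zero; scale to
  # unit variance of the background (outside the particle mask)
  bg <- radialMask2D(N) > maskRadiusFrac * N
  sdev <- sd(out[bg])
  if (sdev <= 0) return(out)
  out / sdev
}

#' Preprocess a whole stack
#'
#' Per-particle phase flip (using the metadata defocus) followed by
#' band-pass filtering and background normalisation; the standard
#' preparation before alignment and classification.
#'
#' @param stack a [ParticleStack-class] with a `defocus_um` metadata
#'   column (CTF skipped if absent or `ctf` is NULL).
#' @param lowA,highA band-pass cutoffs in Angstrom.
#' @param ctf CTF template from [ctfParams()].
#' @param maskRadiusFrac background mask radius fraction.
#' @return a new [ParticleStack-class].
#' @export
preprocessStack <- function(stack, lowA = 175, highA = 4,
                            ctf = ctfParams(pixelA = stack@pixelA),
                            maskRadiusFrac = 0.4) {
  imgs <- particleImages(stack)
  meta <- particleMeta(stack)
  px <- stack@pixelA
  highA <- max(highA, 2 * px)
  doCtf <- !is.null(ctf) && "defocus_um" %in% names(meta)
  for (p in seq_len(dim(imgs)[3])) {
    im <- imgs[, , p]
    if (doCtf) {
      cp <- ctf
      cp$defocusUm <- meta$defocus_um[p]
      im <- phaseFlip(im, cp, pixelA = px)
    }
    imgs[, , p] <- bandpassNormalize(im, lowA, highA, px, maskRadiusFrac)
  }
  ParticleStack(imgs, pixelA = px, meta = meta)
}
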