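# CTF model, phase flipping, binning/boxing and band-pass normalisation.

test_that("the CTF equals -A at DC, stays bounded, and zeros where predicted", {
  cp <- ctfParams(defocusUm = 2, amplitudeContrast = 0.07, pixelA = 2.02)
  expect_equal(ctfEvaluate(cp, 0), -0.07)
  set.seed(1)
  f <- runif(10000, 0, 0.25)
  v <- ctfEvaluate(cp, f)
  expect_true(all(v >= -1 & v <= 1))
  # with no amplitude contrast and negligible Cs, the first zero solves
  # chi(f) = pi, i.e. f = sqrt(1 / (lambda dz))
  cp0 <- ctfParams(defocusUm = 1.5, csMm = 1e-6, amplitudeContrast = 0,
                   pixelA = 2.02)
  lam <- 12.2639 / sqrt(120e3 * (1 + 0.97845e-6 * 120e3))
  fPred <- sqrt(1 / (lam * 1.5e4))
  fZero <- uniroot(function(f) ctfEvaluate(cp0, f), c(fPred * 0.5, fPred * 1.2),
                   tol = 1e-10)$root
  expect_equal(fZero, fPred, tolerance = 1e-6)
})

test_that("ctfParams validates its ranges", {
  expect_error(ctfParams(defocusUm = 0), "defocusUm")
  expect_error(ctfParams(defocusUm = 11), "defocusUm")
  expect_error(ctfParams(amplitudeContrast = 0.5), "amplitudeContrast")
})

test_that("phase flipping is an involution and restores contrast", {
  v <- fixMap("Rs1")
  proj <- projectMap(v, c(20, 90, 0))
  cp <- ctfParams(defocusUm = 2.5, pixelA = 4)
  fr <- sqrt(outer((c(0:32, -31:-1) / 256)^2, (c(0:32, -31:-1) / 256)^2, `+`))
  affected <- Re(fft(fft(proj) * ctfEvaluate(cp, fr), inverse = TRUE)) / 64^2
  flipped <- phaseFlip(affected, cp)
  expect_lt(sqrt(mean((phaseFlip(flipped, cp) - affected)^2)), 1e-10)
  expect_gt(cor(as.numeric(flipped), as.numeric(proj)),
            cor(as.numeric(affected), as.numeric(proj)))
  # CTF with no zero crossing in band: output equals input up to sign
  cpTiny <- ctfParams(defocusUm = 0.01, csMm = 1e-6, pixelA = 4)
  out <- phaseFlip(affected, cpTiny)
  expect_lt(min(sqrt(mean((out - affected)^2)),
                sqrt(mean((out + affected)^2))), 1e-10)
  expect_error(phaseFlip(matrix(0, 4, 6), cp), "square")
})

test_that("binning, box extraction and cropping behave on basic contracts", {
  const <- matrix(3.5, 64, 64)
  expect_true(all(bin2x2(const) == 3.5))
  expect_true(all(cropBox(const, 32) == 3.5))
  expect_equal(dim(bin2x2(const)), c(32, 32))
  expect_error(bin2x2(matrix(0, 5, 5)), "even")
  expect_error(cropBox(const, 128), "exceeds")
  img <- matrix(rnorm(256^2), 256, 256)
  cropped <- cropBox(img, 192)
  expect_equal(sum(cropped), sum(img[33:224, 33:224]))
  box <- extractBox(img, c(100, 120), 64)
  expect_equal(box[33, 33], img[100, 120])
  # binning a period-4 sinusoid attenuates by the boxcar factor cos(pi/4)
  s <- matrix(sin(2 * pi * (0:63) / 4), 64, 64)
  b <- bin2x2(s)
  gain <- sd(b) / sd(s)
  expect_equal(gain, cos(pi / 4), tolerance = 0.01)
})

test_that("band-pass normalisation zeroes the DC and scales the background", {
  set.seed(3)
  img <- matrix(rnorm(256^2, mean = 5), 256, 256)
  out <- bandpassNormalize(img, lowA = 175, highA = 4, pixelA = 2)
  expect_lt(abs(mean(out)), 1e-8)
  x <- seq_len(256) - 1 - 128
  bg <- sqrt(outer(x^2, x^2, `+`)) > 0.4 * 256
  expect_equal(var(out[bg]), 1, tolerance = 1e-6)
  expect_lt(Mod(fft(out)[1, 1]), 1e-6)
  expect_error(bandpassNormalize(img, 175, 3, pixelA = 2), "Nyquist")
})

test_that("the 175 A band edge passes 100 A and blocks 300 A", {
  # box of 600 A so both test wavelengths are grid-commensurate
  N <- 256; px <- 600 / 256
  gain_at <- function(waveA) {
    s <- matrix(sin(2 * pi * (0:(N - 1)) * (N * px / waveA) / N), N, N)
    fr <- sqrt(outer((c(0:(N / 2), -(N / 2 - 1):-1) / (N * px))^2,
                     (c(0:(N / 2), -(N / 2 - 1):-1) / (N * px))^2, `+`))
    g <- conformosort:::bandGain(fr, N, px, 175, 4)
    out <- Re(fft(fft(s) * matrix(g, N, N), inverse = TRUE)) / N^2
    sum(out * s) / sum(s * s)
  }
  expect_equal(gain_at(100), 1, tolerance = 0.02)
  expect_lt(gain_at(300), 0.05)
})

test_that("filters are linear and never add power", {
  set.seed(9)
  a <- matrix(rnorm(64^2), 64, 64)
  b <- matrix(rnorm(64^2), 64, 64)
  f <- function(x) bandpassNormalize(x, 175, 8, pixelA = 4)
  # linearity of the filter core (before normalisation): use the gain path
  fr <- sqrt(outer((c(0:32, -31:-1) / 256)^2, (c(0:32, -31:-1) / 256)^2, `+`))
  g <- matrix(conformosort:::bandGain(fr, 64, 4, 175, 8), 64, 64)
  g[1, 1] <- 0
  filt <- function(x) Re(fft(fft(x) * g, inverse = TRUE)) / 64^2
  expect_lt(max(abs(filt(2 * a - 3 * b) - (2 * filt(a) - 3 * filt(b)))), 1e-10)
  expect_lte(sum(filt(a)^2), sum(a^2))
})

test_that("whole-stack preprocessing runs and standardises backgrounds", {
  st <- simulateStack("Rs1", 4, snr = 0.5, seed = 5)
  out <- preprocessStack(st)
  x <- seq_len(64) - 1 - 32
  bg <- sqrt(outer(x^2, x^2, `+`)) > 0.4 * 64
  for (p in 1:4)
    expect_equal(var(particleImages(out)[, , p][bg]), 1, tolerance = 1e-6)
})
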