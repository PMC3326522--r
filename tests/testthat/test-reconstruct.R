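# Direct Fourier inversion, C7 symmetrisation, FSC and the final filter.

lp3 <- function(g, fmax) {
  N <- dim(g)[1]
  fr <- conformosort:::radialFreqGrid3D(N, 1)
  Re(fft(fft(g) * (fr <= fmax), inverse = TRUE)) / N^3
}

test_that("reconstruction from known orientations recovers the map", {
  set.seed(2)
  v <- fixMap("Rs1")
  nP <- 350
  euler <- cbind(runif(nP, 0, 360), runif(nP, 80, 100), runif(nP, 0, 360))
  imgs <- array(0, c(64, 64, nP))
  for (i in seq_len(nP)) imgs[, , i] <- projectMap(v, euler[i, ])
  rec <- reconstructC7(imgs, euler, NULL, 4)
  msk <- softSphereMask(64, 0.4, 3) > 0.5
  a <- lp3(mapGrid(v), 0.20)[msk]
  b <- lp3(mapGrid(rec), 0.20)[msk]
  expect_gte(cor(a, b), 0.95)
  # recorded shifts are compensated exactly
  nS <- 150
  sh <- matrix(runif(2 * nS, -3, 3), nS, 2)
  for (i in seq_len(nS))
    imgs[, , i] <- conformosort:::ctfShiftApply(projectMap(v, euler[i, ]),
                                                NULL, sh[i, ], 4)
  rec2 <- reconstructC7(imgs[, , seq_len(nS)], euler[seq_len(nS), ], sh, 4)
  expect_gte(cor(a, lp3(mapGrid(rec2), 0.20)[msk]), 0.95)
})

test_that("reconstruction is linear and zero images give a zero map", {
  euler <- cbind(c(0, 45, 90), c(90, 85, 95), c(0, 10, 20))
  z <- array(0, c(32, 32, 3))
  expect_warning(rec <- reconstructC7(z, euler, NULL, 4), "under-determined")
  expect_true(all(mapGrid(rec) == 0))
})

test_that("C7 symmetrisation is consistent with symmetric data", {
  # imposing C7 on a reconstruction of C7-symmetric data barely changes it
  set.seed(3)
  v <- fixMap("Rs1")
  nP <- 200
  euler <- cbind(runif(nP, 0, 360), runif(nP, 80, 100), runif(nP, 0, 360))
  imgs <- array(0, c(64, 64, nP))
  for (i in seq_len(nP)) imgs[, , i] <- projectMap(v, euler[i, ])
  recA <- reconstructC7(imgs, euler, NULL, 4, imposeSymmetry = FALSE)
  recS <- reconstructC7(imgs, euler, NULL, 4, imposeSymmetry = TRUE)
  msk <- softSphereMask(64, 0.4, 3) > 0.5
  a <- lp3(mapGrid(recA), 0.18)[msk]
  sm <- lp3(mapGrid(recS), 0.18)[msk]
  relRMS <- sqrt(mean((sm - a)^2)) / sd(a)
  expect_lt(relRMS, 0.06)
  # the symmetrised map is invariant under a further 360/7 rotation, up
  # to the resampling error of the discrete rotation operator
  g <- lp3(mapGrid(recS), 0.18)
  gRot <- conformosort:::cpp_rotate_vol_z(g, 360 / 7)
  expect_lt(sqrt(mean((gRot[msk] - g[msk])^2)) / sd(g[msk]), 0.06)
})

test_that("FSC is 1 for identical halves and symmetric in its arguments", {
  v <- fixMap("Rs1")
  f <- fscCurve(v, v)
  expect_true(all(abs(f@correlation - 1) < 1e-9))
  set.seed(4)
  a <- array(rnorm(32^3), c(32, 32, 32))
  b <- array(rnorm(32^3), c(32, 32, 32)) + 0.5 * a
  f1 <- fscCurve(a, b, voxelA = 4)
  f2 <- fscCurve(b, a, voxelA = 4)
  expect_equal(f1@correlation, f2@correlation, tolerance = 1e-12)
})

test_that("independent noise reconstructions decorrelate at high frequency", {
  set.seed(5)
  nP <- 80
  euler <- cbind(runif(nP, 0, 360), runif(nP, 80, 100), runif(nP, 0, 360))
  imgs <- array(rnorm(48 * 48 * nP), c(48, 48, nP))
  f <- splitHalfFSC(imgs, euler, NULL, voxelA = 4)
  beyond <- f@shellFreq > 0.25 / (2 * 4)   # beyond 1/4 Nyquist
  expect_lt(mean(abs(f@correlation[beyond])), 0.1)
})

test_that("a planted 12 A band limit is read back from the 0.5 crossing", {
  set.seed(6)
  N <- 64; px <- 4
  fr <- conformosort:::radialFreqGrid3D(N, px)
  keep <- fr <= 1 / 12
  signal <- Re(fft(fft(array(rnorm(N^3), c(N, N, N))) * keep,
                   inverse = TRUE)) / N^3
  sSig <- sd(signal)
  half <- function() signal + array(rnorm(N^3, sd = sSig * 0.45), c(N, N, N))
  f <- fscCurve(half(), half(), voxelA = px)
  expect_equal(resolutionAtThreshold(f, 0.5), 12, tolerance = 1)
})

test_that("threshold crossings interpolate linearly between shells", {
  cv <- new("FSCCurve", shellFreq = c(0.01, 0.02, 0.03, 0.04),
            correlation = c(1, 0.9, 0.3, 0.1), threshold = 0.5)
  # crossing between 0.02 and 0.03 at 0.9 -> 0.3: f = 0.02 + 0.01 * (0.4/0.6)
  expect_equal(resolutionAtThreshold(cv), 1 / (0.02 + 0.01 * (0.4 / 0.6)),
               tolerance = 1e-12)
  # a curve that never drops below threshold reports the band limit
  cv2 <- new("FSCCurve", shellFreq = c(0.01, 0.02), correlation = c(1, 0.9),
             threshold = 0.5)
  expect_equal(resolutionAtThreshold(cv2), 1 / 0.02)
})

test_that("the final amplitude filter follows the 10% low-frequency rule", {
  # 240 A box: 40 A and 12 A are both grid-commensurate wavelengths
  N <- 64; px <- 3.75
  gain_at <- function(waveA) {
    cyc <- N * px / waveA
    s <- array(rep(sin(2 * pi * (0:(N - 1)) * cyc / N), N * N), c(N, N, N))
    out <- mapGrid(finalFilter(DensityMap(s, px), 20, 8.5, 0.1))
    sum(out * s) / sum(s * s)
  }
  expect_equal(gain_at(40), 0.1, tolerance = 0.02)
  expect_equal(gain_at(12), 1.0, tolerance = 0.02)
  # neutral settings give the identity
  set.seed(7)
  g <- array(rnorm(32^3), c(32, 32, 32))
  m <- DensityMap(g, 2.5)
  out <- finalFilter(m, lowA = 20, highA = 2 * 2.5, lowFreqFactor = 1)
  expect_lt(max(abs(mapGrid(out) - g)), 1e-8)
  expect_error(finalFilter(m, 20, 3, 0.1), "Nyquist")
})
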