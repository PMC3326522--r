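# Ground-truth phantom: state library, C7 geometry, density synthesis,
# projection and particle simulation.

test_that("canonical state library carries the published anchors", {
  st <- canonicalStates()
  expect_true(all(unlist(st$T[-1]) == 0))
  expect_equal(st$Rs1$tilt_deg, 35)
  expect_equal(st$Rs_open$elevation_deg - st$Rs2$elevation_deg, 20)
  expect_equal(st$R_ES$twist_deg - st$Rs_open$twist_deg, 100)
  expect_equal(st$Rs_open$elevation_deg / st$R_ES$elevation_deg, 0.7,
               tolerance = 1e-9)
})

test_that("unknown state names and bad hinge axes are rejected", {
  expect_error(buildStateModel("Rz9"), "unknown state")
  sub <- defaultSubunit()
  sub$hinge1_axis <- c(1, 0.5, 0)
  expect_error(buildStateModel("Rs1", "T", subunit = sub), "unit length")
})

test_that("T/T model reproduces the template geometry and C7 closure holds", {
  m <- fixModel("T", "T")
  sub <- defaultSubunit()
  expect_equal(atomCoords(m, ring = "top", subunit = 1),
               unname(as.matrix(sub$atoms[, c("x", "y", "z")])),
               ignore_attr = TRUE, tolerance = 1e-12)
  # rotating any subunit by 360/7 reproduces its neighbour
  for (mm in list(m, fixModel("Rs_open"))) {
    for (k in 1:6) {
      a <- atomCoords(mm, ring = "top", subunit = k) %*% t(rotZ(360 / 7))
      b <- atomCoords(mm, ring = "top", subunit = k + 1)
      expect_lt(max(abs(a - b)), 1e-6)
    }
  }
})

test_that("per-subunit overrides break symmetry and are flagged", {
  m <- buildStateModel("T", "T", topOverrides = list(`2` = "Rs_open"))
  expect_false(m@symmetric)
  a <- atomCoords(m, ring = "top", subunit = 1) %*% t(rotZ(360 / 7))
  b <- atomCoords(m, ring = "top", subunit = 2)
  expect_gt(max(abs(a - b)), 1)
})

test_that("the 35 degree en-bloc tilt and the 20 degree elevation are built in", {
  mT <- fixModel("T"); mRs1 <- fixModel("Rs1")
  blk <- measureDomainMotion(mT, mRs1, "intermediate+apical")
  expect_equal(blk$angle_deg, 35, tolerance = 0.1)
  # apical elevation difference between Rs2 and Rs_open
  el <- measureDomainMotion(fixModel("Rs2"), fixModel("Rs_open"), "apical")
  expect_equal(el$angle_deg, 20, tolerance = 0.1)
})

test_that("apical rotation relative to T increases along the Rs trajectory", {
  mT <- fixModel("T")
  ang <- vapply(c("Rs1", "Rs2", "Rs_open", "R_ES"), function(s)
    measureDomainMotion(mT, fixModel(s), "apical")$angle_deg, numeric(1))
  expect_true(all(diff(ang) > 0))
})

test_that("density synthesis conserves mass and is shift-equivariant", {
  one <- densityFromCoords(matrix(0, 1, 3), mass = 2.5, voxelA = 2,
                           boxVox = 32, resolutionA = 8)
  g <- mapGrid(one)
  expect_equal(as.numeric(which(g == max(g), arr.ind = TRUE)[1, ]),
               c(17, 17, 17))
  expect_equal(sum(g), 2.5, tolerance = 0.01)
  # one-voxel translation shifts the grid exactly
  m <- fixModel("Rs1")
  co <- atomCoords(m)
  v0 <- mapGrid(densityFromCoords(co, 1, 4, 64, 10))
  v1 <- mapGrid(densityFromCoords(sweep(co, 2, c(4, 0, 0), `+`), 1, 4, 64, 10))
  expect_lt(max(abs(v1[2:64, , ] - v0[1:63, , ])), 1e-6 * max(v0))
  expect_equal(sum(v0), nrow(co), tolerance = 0.01)
})

test_that("density synthesis rejects bad geometry requests", {
  co <- atomCoords(fixModel("T"))
  expect_error(densityFromCoords(co, 1, 4, 32, 10), "beyond the box")
  expect_error(densityFromCoords(co, 1, 4, 64, 6), "sub-Nyquist")
})

test_that("T and Rs_open densities are distinguishable at 8 A", {
  a <- as.numeric(mapGrid(fixMap("T")))
  b <- as.numeric(mapGrid(fixMap("Rs_open")))
  expect_lt(cor(a, b), 0.98)
})

test_that("projection conserves mass and a sphere projects isotropically", {
  v <- fixMap("Rs1")
  for (ang in list(c(0, 90, 0), c(33, 85, 120))) {
    p <- projectMap(v, ang)
    expect_equal(sum(p), sum(mapGrid(v)) * voxelSize(v), tolerance = 5e-3)
  }
  # centred Gaussian ball: the radial profile of a projection is the
  # same in every angular sector (the projection of a sphere is
  # rotationally symmetric)
  ball <- densityFromCoords(matrix(0, 1, 3), 1, 4, 48, 40)
  p2 <- projectMap(ball, c(45, 60, 10))
  flip <- c(1, 48:2)
  aniso <- max(abs(p2 - t(p2)), abs(p2 - p2[flip, flip])) / max(p2)
  expect_lt(aniso, 0.01)
})

test_that("C7 symmetry shows as azimuthal periodicity of projections", {
  # smooth rendering so interpolation error stays below the 1% bound
  m <- fixModel("Rs1")
  v <- synthesizeDensity(m, 3, 96, 12)
  pa <- projectMap(v, c(9, 90, 0))
  pb <- projectMap(v, c(9 + 360 / 7, 90, 0))
  expect_lt(sqrt(mean((pa - pb)^2)) / sd(pa), 0.01)
})

test_that("simulated stacks honour the side-view geometry and the seed", {
  st <- simulateStack(c("T", "Rs_open"), 25, snr = 0.5, seed = 7,
                      voxelA = 5, boxVox = 48, resolutionA = 11)
  md <- particleMeta(st)
  expect_true(all(md$theta >= 80 & md$theta <= 100))
  expect_true(all(abs(md$sx) <= 3 & abs(md$sy) <= 3))
  expect_true(all(md$defocus_um >= 0.7 & md$defocus_um <= 3.5))
  st2 <- simulateStack(c("T", "Rs_open"), 25, snr = 0.5, seed = 7,
                       voxelA = 5, boxVox = 48, resolutionA = 11)
  expect_identical(particleImages(st), particleImages(st2))
  st3 <- simulateStack(c("T", "Rs_open"), 25, snr = 0.5, seed = 8,
                       voxelA = 5, boxVox = 48, resolutionA = 11)
  expect_false(identical(particleImages(st), particleImages(st3)))
  expect_error(simulateStack(list(), 10, seed = 1), "empty model list")
  expect_error(simulateStack("T", 0, seed = 1), "positive")
})

test_that("noise-free, shift-free particles equal the CTF-affected projection", {
  st <- simulateStack("Rs1", 2, snr = Inf, seed = 3, shiftMaxPx = 0,
                      voxelA = 4, boxVox = 64, resolutionA = 8)
  md <- particleMeta(st)
  v <- fixMap("Rs1")
  # independent oracle: projection, then CTF modulation in Fourier space
  proj <- projectMap(v, as.numeric(md[1, c("phi", "theta", "psi")]))
  cp <- ctfParams(defocusUm = md$defocus_um[1], pixelA = 4)
  fr <- sqrt(outer((c(0:32, -31:-1) / (64 * 4))^2,
                   (c(0:32, -31:-1) / (64 * 4))^2, `+`))
  oracle <- Re(fft(fft(proj) * ctfEvaluate(cp, fr), inverse = TRUE)) / 64^2
  expect_equal(particleImages(st)[, , 1], oracle, tolerance = 1e-10)
})

test_that("measured stack SNR matches the request within 10%", {
  clean <- simulateStack(c("Rs1", "Rs_open"), 250, snr = Inf, seed = 21,
                         voxelA = 5, boxVox = 48, resolutionA = 11)
  noisy <- simulateStack(c("Rs1", "Rs_open"), 250, snr = 0.3, seed = 21,
                         voxelA = 5, boxVox = 48, resolutionA = 11)
  x <- seq_len(48) - 1 - 24
  mask <- sqrt(outer(x^2, x^2, `+`)) <= 0.4 * 48
  ci <- particleImages(clean); ni <- particleImages(noisy)
  vs <- vn <- numeric(500)
  for (p in 1:500) {
    vs[p] <- var(ci[, , p][mask])
    vn[p] <- var((ni[, , p] - ci[, , p])[mask])
  }
  expect_equal(mean(vs / vn), 0.3, tolerance = 0.1 * 0.3)
})

test_that("the angular sampling reports the C7 asymmetric unit", {
  g <- angularGrid(7, 1, c(80, 90, 100))
  expect_equal(g$extent_deg, 360 / 7)
  expect_true(all(g$grid$phi >= 0 & g$grid$phi < 360 / 7))
})
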