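# Eigenimage analysis, component selection, k-means subdivision, junk
# removal, alignment and competitive multi-reference alignment.

test_that("alignment recovers a planted rotation and identifies references", {
  v <- fixMap("Rs1")
  refs <- list(projectMap(v, c(5, 90, 0)), projectMap(v, c(20, 90, 0)),
               projectMap(v, c(35, 90, 0)))
  part <- conformosort:::cpp_transform_image(refs[[2]], 10, 0, 0)
  al <- alignToReferences(array(part, c(64, 64, 1)), refs,
                          angleStepDeg = 1, maxShiftPx = 0)
  expect_equal(al$reference_id, 2L)
  expect_equal(al$in_plane_deg, 10, tolerance = 1)
  expect_gt(al$score, 0.999)
  expect_error(alignToReferences(array(part, c(64, 64, 1)), list()),
               "empty reference")
})

test_that("noise-free two-state particles all match their own projection", {
  st <- simulateStack(c("T", "Rs_open"), 15, snr = Inf, seed = 2,
                      shiftMaxPx = 0, ctf = NULL)
  md <- particleMeta(st)
  vT <- fixMap("T"); vO <- fixMap("Rs_open")
  refs <- list()
  for (p in seq_len(30)) {
    v <- if (md$state[p] == "T") vT else vO
    refs[[p]] <- projectMap(v, c(md$phi[p], md$theta[p], 0))
  }
  al <- alignToReferences(st, refs, angleStepDeg = 3, maxShiftPx = 0)
  # each particle's best reference must be one generated from its own state
  expect_true(all((al$reference_id <= 15) == (md$state == "T")))
})

test_that("pure-noise scores stay inside the Monte-Carlo null", {
  set.seed(11)
  ref <- projectMap(fixMap("T"), c(10, 90, 0))
  null_imgs <- array(rnorm(64 * 64 * 1000), c(64, 64, 1000))
  nullScores <- alignToReferences(null_imgs, list(ref), angleStepDeg = 30,
                                  maxShiftPx = 0)$score
  probe <- array(rnorm(64 * 64), c(64, 64, 1))
  s <- alignToReferences(probe, list(ref), angleStepDeg = 30,
                         maxShiftPx = 0)$score
  expect_lt(abs(s), quantile(abs(nullScores), 0.99))
})

test_that("eigenimages match a brute-force covariance diagonalisation", {
  set.seed(5)
  imgs <- array(rnorm(16 * 16 * 20), c(16, 16, 20))
  dec <- computeEigenimages(imgs, 8)
  X <- t(matrix(imgs, 256, 20))
  ev <- eigen(cov(X), symmetric = TRUE)
  expect_equal(dec@eigenvalues, ev$values[1:8], tolerance = 1e-8)
  for (j in 1:8) {
    c1 <- as.numeric(dec@components[, , j])
    expect_lt(min(sqrt(sum((c1 - ev$vectors[, j])^2)),
                  sqrt(sum((c1 + ev$vectors[, j])^2))), 1e-8)
  }
  # components are mutually orthogonal
  V <- matrix(dec@components, 256, 8)
  expect_lt(max(abs(crossprod(V) - diag(8))), 1e-8)
  expect_error(computeEigenimages(imgs, 20), "nComponents")
})

test_that("identical images give zero eigenvalues", {
  imgs <- array(rep(matrix(rnorm(64), 8, 8), 10), c(8, 8, 10))
  dec <- computeEigenimages(imgs, 5)
  expect_lt(max(dec@eigenvalues), 1e-10)
})

test_that("a planted apical-annulus difference dominates the first component", {
  set.seed(8)
  N <- 32
  mask <- annulusMask(N, 10, 15)
  blob <- matrix(0, N, N)
  blob[mask] <- 1
  imgs <- array(rnorm(N * N * 60, sd = 0.1), c(N, N, 60))
  state <- rep(0:1, 30)
  for (i in 1:60) imgs[, , i] <- imgs[, , i] + state[i] * blob
  dec <- computeEigenimages(imgs, 5)
  frac <- sum(dec@components[, , 1][mask]^2) / sum(dec@components[, , 1]^2)
  expect_gte(frac, 0.8)
  sel <- selectConformationalEigenimages(dec, mask, 0.5)
  expect_true(1 %in% sel)
  expect_false(any(3:5 %in% sel))
  # threshold 0 selects everything; a homogeneous stack selects nothing
  expect_equal(selectConformationalEigenimages(dec, mask, 0), 1:5)
  # a homogeneous stack (identical images) selects nothing
  flat <- array(rep(matrix(rnorm(N * N), N, N), 10), c(N, N, 10))
  decF <- computeEigenimages(flat, 3)
  expect_length(selectConformationalEigenimages(decF, mask, 0.5), 0)
})

test_that("k-means partitioning recovers planted states", {
  ps <- plantedStack(80, snrPlant = 0.3, seed = 42)
  dec <- computeEigenimages(ps$images, 6)
  part <- msaPartition(ps$images, dec, 1:3, 2, seed = 1)
  cls <- classAssignment(part)
  acc <- mean(cls == ps$state)
  expect_true(acc == 1 || acc == 0)   # exact up to label swap
  expect_equal(classAssignment(msaPartition(ps$images, dec, 1:3, 1)),
               rep(1L, 80))
  expect_error(msaPartition(ps$images, dec, integer(0), 2), "non-empty")
  expect_error(msaPartition(ps$images, dec, 1:3, 100), "subgroups")
})

test_that("ten subgroups on a three-state mixture merge to high purity", {
  ps <- plantedStack(120, snrPlant = 0.3, seed = 43, nStates = 3)
  dec <- computeEigenimages(ps$images, 8)
  part <- msaPartition(ps$images, dec, 1:4, 10, seed = 2)
  cls <- classAssignment(part)
  purity <- sum(vapply(1:10, function(k) {
    if (!any(cls == k)) return(0L)
    max(table(ps$state[cls == k]))
  }, integer(1))) / length(cls)
  expect_gte(purity, 0.9)
})

test_that("junk filtering removes planted junk and keeps true particles", {
  set.seed(14)
  st <- simulateStack(c("T", "Rs_open"), 45, snr = 1, seed = 14,
                      shiftMaxPx = 0, ctf = NULL)
  imgs <- particleImages(st)
  njunk <- 10
  junkImgs <- array(rnorm(64 * 64 * njunk, sd = sd(imgs)), c(64, 64, njunk))
  allImgs <- array(0, c(64, 64, 100))
  allImgs[, , 1:90] <- imgs
  allImgs[, , 91:100] <- junkImgs
  meta <- data.frame(index = 1:100,
                     isJunk = c(rep(FALSE, 90), rep(TRUE, njunk)))
  big <- ParticleStack(allImgs, 4, meta)
  # classes: group junk with junk by construction-free k-means on eigens
  dec <- computeEigenimages(big, 6)
  part <- msaPartition(big, dec, 1:6, 12, seed = 3)
  refs <- lapply(seq(0, 48, by = 8), function(phi)
    projectMap(fixMap("T"), c(phi, 90, 0)))
  jf <- junkFilter(big, part, refs, threshold = 0.4)
  removedJunk <- sum(meta$isJunk[jf$removed])
  removedTrue <- length(jf$removed) - removedJunk
  expect_gte(removedJunk / njunk, 0.9)
  expect_lte(removedTrue / 90, 0.02)
  # permissive threshold removes nothing
  jf0 <- junkFilter(big, part, refs, threshold = -1)
  expect_length(jf0$removed, 0)
  expect_warning(junkFilter(big, part, refs, threshold = 1),
                 "removes every class")
  # retained particles keep their labels when the junk class is deleted
  keptBefore <- classAssignment(part)[-jf$removed]
  keptAfter <- classAssignment(jf$partition)[classAssignment(jf$partition) > 0]
  expect_identical(keptBefore, keptAfter)
})

test_that("competitive alignment converges immediately on noise-free data", {
  st <- simulateStack(c("T", "Rs_open"), 30, snr = Inf, seed = 6,
                      shiftMaxPx = 0, ctf = NULL)
  prep <- standardizeImages(st)
  refs <- list(fixMap("T"), fixMap("Rs_open"))
  comp <- competitiveAlign(prep, refs, maxIter = 5, psiRefineDeg = 0,
                           shiftRefinePx = 0,
                           inPlaneDeg = seq(0, 357, by = 3))
  md <- particleMeta(st)
  expect_equal(classAssignment(comp$partition),
               ifelse(md$state == "T", 1L, 2L))
  hist <- convergenceHistory(comp$partition)
  expect_equal(hist[2], 0)       # nothing moves once assigned
  # once the references come from reconstructions the assignment cost
  # stays flat (bounded by the reconstruction-artifact floor)
  if (length(comp$cost) > 2)
    expect_true(all(diff(comp$cost[-1]) <= 2e-3))
})

test_that("the termination contract honours stabilityTol and maxIter", {
  st <- simulateStack(c("T", "Rs_open"), 8, snr = Inf, seed = 6,
                      shiftMaxPx = 0, ctf = NULL)
  prep <- standardizeImages(st)
  refs <- list(fixMap("T"), fixMap("Rs_open"))
  comp <- competitiveAlign(prep, refs, maxIter = 4, stabilityTol = 0,
                           psiRefineDeg = 0, shiftRefinePx = 0,
                           inPlaneDeg = seq(0, 357, by = 3))
  expect_length(convergenceHistory(comp$partition), 4)
  expect_error(competitiveAlign(prep, refs[1]), "at least 2")
})
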