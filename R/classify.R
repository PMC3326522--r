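# Eigenimage-based statistical sorting: alignment to references,
# principal-component eigenimages, variance-localised component
# selection, k-means subdivision, junk removal and iterative competitive
# multi-reference alignment with a stability stopping rule.

#' Align particles to reference images
#'
#' Exhaustive search over the discrete grid of in-plane rotations and
#' integer shifts, for every reference: each particle gets the (rotation,
#' shift, reference) triple maximising the normalised cross-correlation.
#'
#' @param stack a [ParticleStack-class] or N x N x P array.
#' @param references list of reference images (or N x N x R array).
#' @param angleStepDeg in-plane rotation step (degrees; the final
#'   protocol uses 1).
#' @param maxShiftPx translation search radius in pixels (0 = rotations
#'   only).
#' @param angles explicit angle list (overrides `angleStepDeg`).
#' @return data.frame: reference_id, in_plane_deg, shift_x_px, shift_y_px,
#'   score.
#' @export
alignToReferences <- function(stack, references, angleStepDeg = 1,
                              maxShiftPx = 4, angles = NULL) {
  parts <- if (is(stack, "ParticleStack")) particleImages(stack) else stack
  if (is.list(references) && length(references) == 0)
    stop("empty reference list")
  refs <- asImageArray(references)
  if (dim(refs)[3] == 0) stop("empty reference list")
  if (is.null(angles)) angles <- seq(0, 360 - angleStepDeg, by = angleStepDeg)
  res <- cpp_align(parts, refs, angles, as.integer(maxShiftPx))
  data.frame(reference_id = as.integer(res[, 1]), in_plane_deg = res[, 2],
             shift_x_px = res[, 3], shift_y_px = res[, 4], score = res[, 5])
}

asImageArray <- function(x) {
  if (is.list(x)) {
    N <- nrow(x[[1]])
    out <- array(0, c(N, N, length(x)))
    for (i in seq_along(x)) out[, , i] <- x[[i]]
    out
  } else if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

#' Undo an alignment: bring particles into the reference frame
#'
#' Applies the inverse of the found (rotation, shift) to each particle so
#' the stack is in register with the references.
#'
#' @param stack a [ParticleStack-class] or array.
#' @param params alignment table from [alignToReferences()].
#' @return object of the same type with transformed images (alignment
#'   columns appended to the metadata for a stack).
#' @export
applyAlignment <- function(stack, params) {
  isStack <- is(stack, "ParticleStack")
  parts <- if (isStack) particleImages(stack) else stack
  out <- parts
  for (p in seq_len(dim(parts)[3])) {
    a <- params$in_plane_deg[p]
    s <- c(params$shift_x_px[p], params$shift_y_px[p])
    u <- -as.numeric(rotZ(-a)[1:2, 1:2] %*% s)
    out[, , p] <- cpp_transform_image(parts[, , p], -a, u[1], u[2])
  }
  if (isStack) {
    meta <- particleMeta(stack)
    meta$aligned_deg <- params$in_plane_deg
    meta$aligned_sx <- params$shift_x_px
    meta$aligned_sy <- params$shift_y_px
    meta$aligned_ref <- params$reference_id
    meta$aligned_score <- params$score
    ParticleStack(out, stack@pixelA, meta)
  } else out
}

#' Standardise every image to zero mean and unit variance
#'
#' Removes per-particle amplitude variation (which otherwise leaks into
#' the leading eigenimages) before statistical analysis.
#'
#' @param stack a [ParticleStack-class] or array.
#' @return object of the same type.
#' @export
standardizeImages <- function(stack) {
  isStack <- is(stack, "ParticleStack")
  imgs <- if (isStack) particleImages(stack) else stack
  for (p in seq_len(dim(imgs)[3])) {
    im <- imgs[, , p]
    s <- sd(im)
    imgs[, , p] <- if (s > 0) (im - mean(im)) / s else im - mean(im)
  }
  if (isStack) ParticleStack(imgs, stack@pixelA, particleMeta(stack)) else imgs
}

#' Eigenimages of an aligned stack
#'
#' Principal component analysis of the pixel covariance (the classical
#' multivariate statistical analysis of aligned particle images), via the
#' Gram-matrix route when particles are fewer than pixels.  Components
#' are unit-norm and orthogonal; eigenvalues are the variances along
#' them, sorted descending.
#'
#' @param stack a [ParticleStack-class] or N x N x P array.
#' @param nComponents number of components to keep (< number of images).
#' @return An [EigenDecomposition-class].
#' @export
computeEigenimages <- function(stack, nComponents = 10) {
  parts <- if (is(stack, "ParticleStack")) particleImages(stack) else stack
  d <- dim(parts)
  n <- d[3]
  if (nComponents >= n) stop("nComponents must be < number of images")
  X <- t(matrix(parts, d[1] * d[2], n))      # n x p
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  G <- tcrossprod(Xc) / (n - 1)              # n x n Gram matrix
  eg <- eigen(G, symmetric = TRUE)
  k <- nComponents
  ev <- pmax(eg$values[seq_len(k)], 0)
  comps <- array(0, c(d[1], d[2], k))
  for (j in seq_len(k)) {
    v <- as.numeric(crossprod(Xc, eg$vectors[, j]))
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    comps[, , j] <- matrix(v, d[1], d[2])
  }
  new("EigenDecomposition", meanImage = matrix(mu, d[1], d[2]),
      components = comps, eigenvalues = ev)
}

#' Project particles onto eigenimages
#'
#' @param stack a [ParticleStack-class] or array.
#' @param decomp an [EigenDecomposition-class].
#' @param componentIds which components (default all).
#' @return P x k score matrix.
#' @export
eigenScores <- function(stack, decomp, componentIds = NULL) {
  parts <- if (is(stack, "ParticleStack")) particleImages(stack) else stack
  d <- dim(parts)
  if (is.null(componentIds))
    componentIds <- seq_along(decomp@eigenvalues)
  X <- t(matrix(parts, d[1] * d[2], d[3]))
  Xc <- sweep(X, 2, as.numeric(decomp@meanImage))
  V <- matrix(decomp@components, d[1] * d[2],
              length(decomp@eigenvalues))[, componentIds, drop = FALSE]
  Xc %*% V
}

#' Annular pixel mask
#'
#' @param N image side.
#' @param rminPx,rmaxPx annulus radii in pixels (from the image centre).
#' @return logical N x N matrix.
#' @export
annulusMask <- function(N, rminPx, rmaxPx) {
  r <- radialMask2D(N)
  r >= rminPx & r <= rmaxPx
}

#' Select conformational eigenimages by variance localisation
#'
#' Conformational variability of the complexes localises at the apical
#' layers (the top and bottom of the side view), while misalignment
#' components spread over the whole particle.  A component is selected
#' when the fraction of its power inside the mask exceeds the threshold.
#' An empty selection signals a homogeneous stack.
#'
#' @param decomp an [EigenDecomposition-class].
#' @param mask logical matrix (e.g. [annulusMask()]).
#' @param threshold in-mask power fraction required (default 0.5;
#'   0 selects every component with any in-mask power).
#' @return integer component ids (possibly empty).
#' @export
selectConformationalEigenimages <- function(decomp, mask, threshold = 0.5) {
  if (!all(dim(mask) == dim(decomp@meanImage)))
    stop("mask dimensions do not match the images")
  k <- length(decomp@eigenvalues)
  frac <- vapply(seq_len(k), function(j) {
    comp <- decomp@components[, , j]
    tot <- sum(comp^2)
    if (tot <= 0) return(0)
    sum(comp[mask]^2) / tot
  }, numeric(1))
  which(frac > threshold)
}

#' Partition a stack by k-means in eigenspace
#'
#' Particles are clustered on their coordinates along the selected
#' components only; deterministic given the seed.
#'
#' @param stack a [ParticleStack-class] or array.
#' @param decomp an [EigenDecomposition-class].
#' @param selectedIds component ids (from
#'   [selectConformationalEigenimages()]); must be non-empty.
#' @param nSubgroups number of classes.
#' @param seed RNG seed for the k-means starts.
#' @return A [ClassPartition-class].
#' @export
msaPartition <- function(stack, decomp, selectedIds, nSubgroups, seed = 1) {
  if (length(selectedIds) == 0) stop("selectedIds must be non-empty")
  sc <- eigenScores(stack, decomp, selectedIds)
  if (nSubgroups > nrow(sc)) stop("more subgroups than images")
  if (nSubgroups == 1L) return(ClassPartition(rep(1L, nrow(sc))))
  set.seed(seed)
  km <- kmeans(sc, centers = nSubgroups, nstart = 10, iter.max = 100)
  ClassPartition(km$cluster)
}

#' Remove junk classes
#'
#' Class averages that do not resemble any reference projection are
#' dropped: a class is rejected when its average's best normalised
#' cross-correlation against every reference (over in-plane rotations)
#' stays below the threshold.  Removed particles go to the junk class (0).
#'
#' @param stack a [ParticleStack-class].
#' @param partition a [ClassPartition-class].
#' @param references reference projections (list or array).
#' @param threshold CC-to-reference threshold; 1.0 removes everything
#'   (degenerate, warned).
#' @param angleStepDeg rotation search step for the class-average match.
#' @return list: `stack` (reduced), `partition` (with junk marked),
#'   `removed` (particle indices), `classCC` (per-class best CC).
#' @export
junkFilter <- function(stack, partition, references, threshold = 0.5,
                       angleStepDeg = 5) {
  if (threshold >= 1) warning("threshold 1.0 removes every class")
  asg <- classAssignment(partition)
  ids <- sort(unique(asg[asg > 0L]))
  imgs <- particleImages(stack)
  N <- dim(imgs)[1]
  avgs <- array(0, c(N, N, length(ids)))
  for (i in seq_along(ids))
    avgs[, , i] <- apply(imgs[, , asg == ids[i], drop = FALSE], c(1, 2), mean)
  al <- alignToReferences(avgs, references, angleStepDeg = angleStepDeg,
                          maxShiftPx = 2)
  classCC <- setNames(al$score, ids)
  bad <- ids[classCC < threshold]
  removed <- which(asg %in% bad)
  asg2 <- asg
  asg2[removed] <- 0L
  keep <- asg2 > 0L
  meta <- particleMeta(stack)[keep, , drop = FALSE]
  out <- ParticleStack(imgs[, , keep, drop = FALSE], stack@pixelA, meta)
  list(stack = out, partition = ClassPartition(asg2), removed = removed,
       classCC = classCC)
}

#' Competitive multi-reference alignment
#'
#' The iterative loop that separates conformers: reproject each 3D
#' reference over the side-view angular grid, assign every particle to
#' the best-scoring reference and orientation, reconstruct each class,
#' and repeat until the fraction of particles changing class falls below
#' the stability tolerance (or `maxIter` is hit).  The full history is
#' returned so callers can watch for class bleeding under over-iteration
#' (assignments can drift if the loop is left to run long after
#' stabilising).  Ties go to the lowest reference id.
#'
#' @param stack a [ParticleStack-class] (pre-processed, roughly centred).
#' @param initialReferences list of [DensityMap-class] references (>= 2).
#' @param aziStepDeg azimuth step over the C7 asymmetric unit.
#' @param tiltSetDeg tilt values of the reprojection grid.
#' @param inPlaneDeg in-plane rotation offsets searched around each
#'   reprojection.
#' @param maxShiftPx translation search radius (0 when the stack is
#'   already shift-aligned).
#' @param shiftRefinePx after each assignment, re-centre every particle
#'   on its matched template by Fourier cross-correlation within this
#'   radius (sub-pixel, via the exact Fourier shift); 0 disables.  The
#'   refined images are returned and used for the reconstructions, so
#'   registration sharpens as the references improve.
#' @param stabilityTol stop when the moved fraction drops below this.
#' @param maxIter iteration cap.
#' @param nFoldSym symmetry order for the per-class reconstructions.
#' @return list: `partition` ([ClassPartition-class] with history),
#'   `maps` (per-class reconstructions), `orientations` (per-particle
#'   phi/theta/psi/shift/score), `cost` (per-iteration mean negative CC),
#'   `stack` (the shift-refined [ParticleStack-class]),
#'   `residualShifts` (cumulative per-particle refinement shifts).
#' @export
competitiveAlign <- function(stack, initialReferences, aziStepDeg = 2,
                             tiltSetDeg = seq(80, 100, by = 2),
                             inPlaneDeg = seq(-9, 9, by = 3),
                             ctf = NULL, nDefocusBins = 10,
                             shiftRefinePx = 2, psiRefineDeg = 2,
                             refFilterA = NULL, refMomentum = 0,
                             stabilityTol = 0.01,
                             maxIter = 8, nFoldSym = 7) {
  if (length(initialReferences) < 2) stop("need at least 2 references")
  orig <- particleImages(stack)
  N <- dim(orig)[1]
  P <- dim(orig)[3]
  px <- stack@pixelA
  gridF <- angularGrid(nFoldSym, aziStepDeg, tiltSetDeg)$grid
  GF <- nrow(gridF)
  maps <- initialReferences
  K <- length(maps)
  assign_prev <- rep(0L, P)
  history <- numeric(0)
  cost <- numeric(0)
  totalShift <- matrix(0, P, 2)
  psiCum <- rep(0, P)
  # defocus bins for CTF-matched scoring templates
  meta <- particleMeta(stack)
  useCtf <- !is.null(ctf) && "defocus_um" %in% names(meta)
  if (useCtf) {
    qs <- quantile(meta$defocus_um, probs = seq(0, 1, length.out = nDefocusBins + 1))
    bin_of <- pmin(nDefocusBins,
                   pmax(1L, findInterval(meta$defocus_um, qs, rightmost.closed = TRUE)))
    binDef <- vapply(seq_len(nDefocusBins), function(b)
      mean(meta$defocus_um[bin_of == b]), numeric(1))
    fr2 <- radialFreqGrid2D(N, px)
  } else {
    bin_of <- rep(1L, P)
    binDef <- NA_real_
  }
  work <- orig
  registerWork <- function() {
    for (p in seq_len(P)) {
      im <- orig[, , p]
      if (psiCum[p] != 0) im <- cpp_transform_image(im, -psiCum[p], 0, 0)
      if (any(totalShift[p, ] != 0))
        im <- ctfShiftApply(im, NULL, totalShift[p, ], 1)
      work[, , p] <<- im
    }
  }
  project_set <- function() {
    refs <- array(0, c(N, N, GF * K))
    for (k in seq_len(K)) {
      vol <- mapGrid(maps[[k]])
      for (g in seq_len(GF))
        refs[, , (k - 1) * GF + g] <-
          cpp_project(vol, eulerMatrix(c(gridF$phi[g], gridF$theta[g], 0))) * px
    }
    refs
  }
  orient <- NULL
  for (it in seq_len(maxIter)) {
    refsF <- project_set()
    # at the first pass, bootstrap in-plane registration with a coarse
    # exhaustive search; later iterations only refine continuously
    if (it == 1 && length(inPlaneDeg) > 1) {
      al0 <- cpp_align(orig, refsF[, , seq(1, GF * K, by = max(1, GF %/% 16)),
                                   drop = FALSE],
                       inPlaneDeg, 0L)
      psiCum <- al0[, 2]
    }
    registerWork()
    # uprighted particles and their exact 180-degree flips (the side-view
    # flip ambiguity is re-checked every iteration)
    up <- matrix(0, P, N * N)
    upF <- matrix(0, P, N * N)
    flipIdx <- c(1, N:2)
    for (p in seq_len(P)) {
      u <- work[, , p]
      u <- u - mean(u)
      nv <- sqrt(sum(u * u))
      if (nv > 0) u <- u / nv
      up[p, ] <- u
      upF[p, ] <- u[flipIdx, flipIdx]
    }
    # scoring templates, optionally attenuated by each defocus bin's |CTF|
    S <- matrix(-2, P, GF * K)
    SF <- matrix(-2, P, GF * K)
    for (b in sort(unique(bin_of))) {
      sel <- which(bin_of == b)
      refsB <- refsF
      if (useCtf) {
        cp <- ctf
        cp$defocusUm <- binDef[b]
        w <- abs(ctfEvaluate(cp, fr2))
        for (j in seq_len(GF * K))
          refsB[, , j] <- Re(fft(fft(refsF[, , j]) * w, inverse = TRUE)) / (N * N)
      }
      FM <- matrix(refsB, N * N, GF * K)
      FM <- sweep(FM, 2, colMeans(FM))
      nrm <- sqrt(colSums(FM^2))
      nrm[nrm == 0] <- 1
      FM <- sweep(FM, 2, nrm, `/`)
      S[sel, ] <- up[sel, , drop = FALSE] %*% FM
      SF[sel, ] <- upF[sel, , drop = FALSE] %*% FM
      if (!useCtf) break
    }
    # paired decision: the orientation (and flip) is chosen once per
    # particle, on the class-averaged score, then the class comparison is
    # made at that same orientation -- otherwise the per-class
    # maximisation over hundreds of orientations drowns the small
    # conformational signal in selection noise
    dim(S) <- c(P, GF, K)
    dim(SF) <- c(P, GF, K)
    Savg <- rowMeans(S, dims = 2)
    SavgF <- rowMeans(SF, dims = 2)
    g_of <- max.col(Savg, ties.method = "first")
    g_ofF <- max.col(SavgF, ties.method = "first")
    flip <- SavgF[cbind(seq_len(P), g_ofF)] > Savg[cbind(seq_len(P), g_of)]
    if (any(flip)) {
      g_of[flip] <- g_ofF[flip]
      S[flip, , ] <- SF[flip, , ]
      psiCum[flip] <- psiCum[flip] + 180
      registerWork()
    }
    Sg <- matrix(0, P, K)
    for (k in seq_len(K)) Sg[, k] <- S[cbind(seq_len(P), g_of, k)]
    k_of <- max.col(Sg, ties.method = "first")
    score <- Sg[cbind(seq_len(P), k_of)]
    ridx <- (k_of - 1L) * GF + g_of
    moved <- mean(k_of != assign_prev)
    history <- c(history, moved)
    cost <- c(cost, mean(-score))
    assign_prev <- k_of
    # continuous registration refinement against the CONSENSUS template
    # (the class-averaged reprojection at the chosen orientation):
    # refining against the chosen class's own template would bias the
    # next class decision towards it
    if (psiRefineDeg > 0 || shiftRefinePx > 0) {
      for (p in seq_len(P)) {
        tmpl <- refsF[, , g_of[p]]
        if (K > 1) {
          for (k in 2:K) tmpl <- tmpl + refsF[, , (k - 1) * GF + g_of[p]]
          tmpl <- tmpl / K
        }
        wp <- work[, , p]
        if (psiRefineDeg > 0) {
          f1 <- function(da) {
            tt <- cpp_transform_image(tmpl, da, 0, 0)
            tt <- tt - mean(tt)
            sum(wp * tt) / sqrt(sum(tt * tt))
          }
          g <- goldenMax(f1, -psiRefineDeg, psiRefineDeg, tol = 0.2)
          if (abs(g$x) > 0.05) psiCum[p] <- psiCum[p] + g$x
        }
        if (shiftRefinePx > 0) {
          s <- fourierShiftPeak(wp, tmpl, shiftRefinePx)
          totalShift[p, ] <- totalShift[p, ] + s
        }
      }
      registerWork()
    }
    orient <- data.frame(
      class = k_of,
      phi = gridF$phi[g_of], theta = gridF$theta[g_of],
      psi = rep(0, P), sx = rep(0, P), sy = rep(0, P), score = score)
    for (k in seq_len(K)) {
      sel <- which(k_of == k)
      if (length(sel) == 0) {
        warning("class ", k, " emptied out at iteration ", it)
        next
      }
      newMap <- reconstructC7(work[, , sel, drop = FALSE],
                              as.matrix(orient[sel, c("phi", "theta", "psi")]),
                              NULL, voxelA = px, nFoldSym = nFoldSym)
      # optional denoising of the evolving references: low-pass filter
      # and/or blending with the previous iteration's reference
      if (!is.null(refFilterA) && refFilterA > 2 * px)
        newMap <- finalFilter(newMap, lowA = Inf, highA = refFilterA,
                              lowFreqFactor = 1)
      if (refMomentum > 0 && it > 1) {
        old <- mapGrid(maps[[k]])
        sNew <- sd(as.numeric(mapGrid(newMap)))
        sOld <- sd(as.numeric(old))
        if (sOld > 0 && sNew > 0)
          newMap@grid <- refMomentum * old * (sNew / sOld) +
            (1 - refMomentum) * mapGrid(newMap)
      }
      maps[[k]] <- newMap
    }
    if (moved < stabilityTol && it > 1) break
  }
  list(partition = ClassPartition(assign_prev, history = history),
       maps = maps, orientations = orient, cost = cost,
       stack = ParticleStack(work, stack@pixelA, particleMeta(stack)),
       registration = data.frame(psi_deg = psiCum,
                                 sx_px = totalShift[, 1],
                                 sy_px = totalShift[, 2]),
       residualShifts = totalShift)
}

# sub-pixel translation between an image and a template by Fourier
# cross-correlation: integer peak within `radius`, then parabolic
# interpolation; returns the shift to APPLY to the image to register it
# onto the template.
fourierShiftPeak <- function(img, tmpl, radius) {
  N <- nrow(img)
  cc <- Re(fft(fft(img) * Conj(fft(tmpl)), inverse = TRUE))
  win <- c(seq_len(radius + 1), (N - radius + 1):N)
  sub <- cc[win, win]
  ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  toOff <- function(i) if (i <= radius + 1) i - 1 else i - 2 * radius - 2
  dx <- toOff(ij[1]); dy <- toOff(ij[2])
  # parabolic sub-pixel refinement around the integer peak
  pk <- function(d1, d0, d2) {
    den <- d1 - 2 * d0 + d2
    if (abs(den) < 1e-12) return(0)
    max(-0.5, min(0.5, 0.5 * (d1 - d2) / den))
  }
  at <- function(dx, dy) cc[(dx %% N) + 1, (dy %% N) + 1]
  sx <- dx + pk(at(dx - 1, dy), at(dx, dy), at(dx + 1, dy))
  sy <- dy + pk(at(dx, dy - 1), at(dx, dy), at(dx, dy + 1))
  c(-sx, -sy)
}
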