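# End-to-end orchestration: simulate -> preprocess -> orient -> eigen
# sort -> competitive alignment -> reconstruct -> hinge fit -> quantify,
# a desk-scale version of the hierarchical sorting procedure.

#' Pipeline configuration
#'
#' All knobs of [runPipeline()] with their defaults.  The default
#' geometry (64^3 voxels at 4 Angstrom) keeps the flagship simulation in
#' the minutes range; the acquisition-scale geometry (192^2 at 2.02
#' Angstrom) is available by overriding `boxVox` / `voxelA`.
#'
#' @param seed master seed; with the config it determines every output.
#' @param states canonical state names to mix.
#' @param nPerState particles per state.
#' @param snr simulated signal-to-noise ratio.
#' @param boxVox,voxelA,resolutionA rendering geometry.
#' @param shiftMaxPx simulated shift range.
#' @param bootstrapState reference state for the initial orientation
#'   alignment (default: middle of `states`).
#' @param nComponents eigenimages computed.
#' @param annulusA conformational-variance annulus (Angstrom radii).
#' @param eigenThreshold in-mask power fraction for component selection.
#' @param junkThreshold class-average CC threshold (0 disables junk
#'   removal).
#' @param aziStepDeg,tiltSetDeg,inPlaneDeg,stabilityTol,maxIter
#'   competitive-alignment options.
#' @param fitFree hinge parameters refined per class (preset name or
#'   vector).
#' @param modelRounds rounds of model-regularised competitive alignment:
#'   after the free-reference loop converges, each class map is
#'   hinge-fitted and the fitted models are synthesised into clean,
#'   hinge-manifold-constrained references for a further assignment pass.
#'   This removes the reconstruction noise that otherwise dominates the
#'   between-class difference at low SNR.
#' @param modelFitFree hinge parameters fitted for those reference models
#'   (kept to the informative ones so nuisance parameters cannot create
#'   spurious between-class differences).
#' @param computeFSC compute per-class split-half FSC resolutions (skippable
#'   for benchmark sweeps that only use the partition).
#' @param outdir output directory (NULL: nothing written).
#' @return config list.
#' @export
pipelineConfig <- function(seed = 17, states = c("Rs1", "Rs2", "Rs_open"),
                           nPerState = 500, snr = 0.1, boxVox = 64,
                           voxelA = 4, resolutionA = 8, shiftMaxPx = 3,
                           bootstrapState = NULL, nComponents = 8,
                           annulusA = c(48, 82), eigenThreshold = 0.5,
                           junkThreshold = 0, aziStepDeg = 4,
                           tiltSetDeg = c(84, 90, 96),
                           inPlaneDeg = seq(-9, 9, by = 3),
                           stabilityTol = 0.01, maxIter = 8,
                           fitFree = "open", modelRounds = 3,
                           modelFitFree = c("tilt_deg", "elevation_deg",
                                            "radial_shift_A"),
                           computeFSC = TRUE, outdir = NULL) {
  if (is.null(bootstrapState))
    bootstrapState <- states[ceiling(length(states) / 2)]
  as.list(environment())
}

majorityMap <- function(trueState, cls) {
  ids <- sort(unique(cls[cls > 0]))
  m <- vapply(ids, function(k) {
    tt <- table(trueState[cls == k])
    names(tt)[which.max(tt)]
  }, character(1))
  names(m) <- ids
  m
}

#' Run the full sorting pipeline
#'
#' Executes every stage on a simulated multi-conformer data set and
#' returns a report with the confusion matrix against ground truth, the
#' per-class FSC resolutions, the recovered hinge parameters, and the
#' salt-bridge state assignment of each fitted class.
#'
#' @param config from [pipelineConfig()].
#' @return report list (see Details); with `config$outdir` set, all
#'   intermediates (stacks, maps, tables) are written there.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  cf <- config
  t0 <- Sys.time()
  log_ <- function(...) message(sprintf("[pipeline +%.0fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)

  log_("simulate: ", length(cf$states), " states x ", cf$nPerState,
       " particles, snr ", cf$snr)
  stack <- simulateStack(cf$states, cf$nPerState, snr = cf$snr,
                         seed = cf$seed, voxelA = cf$voxelA,
                         boxVox = cf$boxVox, resolutionA = cf$resolutionA,
                         shiftMaxPx = cf$shiftMaxPx)
  log_("preprocess: phase flip + band-pass + normalise")
  prep <- preprocessStack(stack)

  log_("orient: bootstrap alignment against ", cf$bootstrapState)
  bootModel <- buildStateModel(cf$bootstrapState,
    if (startsWith(cf$bootstrapState, "Rd")) cf$bootstrapState else "T")
  bootMap <- synthesizeDensity(bootModel, cf$voxelA, cf$boxVox, cf$resolutionA)
  # stage A: one global reference fixes in-plane rotation and shift
  refA <- projectMap(bootMap, c(180 / 7, 90, 0))
  alA <- alignToReferences(prep, list(refA), angleStepDeg = 3,
                           maxShiftPx = ceiling(cf$shiftMaxPx) + 1)
  aligned <- applyAlignment(prep, alA)
  # stage B: orientation assignment over the side-view grid.  The
  # in-plane search includes +180 degree candidates so that particles
  # whose ATP ring points the wrong way (the side-view flip ambiguity,
  # unresolvable against a symmetric reference) are caught here -- this
  # requires an asymmetric bootstrap state.  The stack is then fully
  # derotated so everything downstream works on upright particles.
  grid <- angularGrid(7, cf$aziStepDeg, cf$tiltSetDeg)$grid
  refsB <- lapply(seq_len(nrow(grid)), function(g)
    projectMap(bootMap, c(grid$phi[g], grid$theta[g], 0)))
  alB <- alignToReferences(aligned, refsB, maxShiftPx = 0,
                           angles = c(cf$inPlaneDeg, cf$inPlaneDeg + 180))
  aligned <- applyAlignment(aligned, transform(alB, shift_x_px = 0,
                                               shift_y_px = 0))
  aligned <- standardizeImages(aligned)
  orient0 <- data.frame(phi = grid$phi[alB$reference_id],
                        theta = grid$theta[alB$reference_id],
                        psi = 0)

  log_("eigenimages: ", cf$nComponents, " components")
  dec <- computeEigenimages(aligned, cf$nComponents)
  mask <- annulusMask(cf$boxVox, cf$annulusA[1] / cf$voxelA,
                      cf$annulusA[2] / cf$voxelA)
  sel <- selectConformationalEigenimages(dec, mask, cf$eigenThreshold)
  if (length(sel) == 0) {
    warning("no conformational eigenimages selected; using leading components")
    sel <- seq_len(min(4, cf$nComponents))
  }
  log_("msa partition: components ", paste(sel, collapse = ","))
  part0 <- msaPartition(aligned, dec, sel, length(cf$states), seed = cf$seed)

  junk <- NULL
  work <- aligned
  asg0 <- classAssignment(part0)
  orientW <- orient0
  if (cf$junkThreshold > 0) {
    log_("junk filter at CC ", cf$junkThreshold)
    junk <- junkFilter(aligned, part0, refsB, cf$junkThreshold)
    work <- junk$stack
    keep <- classAssignment(junk$partition) > 0
    asg0 <- asg0[keep]
    orientW <- orient0[keep, , drop = FALSE]
  }

  log_("initial class reconstructions")
  imgs <- particleImages(work)
  maps0 <- lapply(sort(unique(asg0)), function(k) {
    selK <- which(asg0 == k)
    reconstructC7(imgs[, , selK, drop = FALSE],
                  as.matrix(orientW[selK, ]), NULL, cf$voxelA)
  })
  log_("competitive alignment (tol ", cf$stabilityTol, ", max ",
       cf$maxIter, " iterations)")
  comp <- competitiveAlign(work, maps0, inPlaneDeg = cf$inPlaneDeg,
                           ctf = ctfParams(pixelA = cf$voxelA),
                           refMomentum = 0.5,
                           stabilityTol = cf$stabilityTol,
                           maxIter = cf$maxIter)
  if (cf$modelRounds > 0) {
    for (round in seq_len(cf$modelRounds)) {
      log_("model-regularised references, round ", round)
      refs <- lapply(comp$maps, function(m) {
        fit <- hingeRefine(m, free = cf$modelFitFree, nIter = 2,
                           resolutionA = cf$resolutionA)
        synthesizeDensity(fit$model, cf$voxelA, cf$boxVox, cf$resolutionA)
      })
      comp <- competitiveAlign(comp$stack, refs, inPlaneDeg = 0,
                               ctf = ctfParams(pixelA = cf$voxelA),
                               maxIter = 1)
    }
  }
  cls <- classAssignment(comp$partition)
  imgs <- particleImages(comp$stack)   # registration-refined images
  work <- comp$stack

  log_("per-class FSC, filtering and hinge fits")
  classes <- sort(unique(cls[cls > 0]))
  fits <- list()
  fscRes <- numeric(0)
  mapsF <- list()
  for (k in classes) {
    selK <- which(cls == k)
    ori <- comp$orientations[selK, ]
    if (cf$computeFSC && length(selK) >= 4) {
      fsc <- splitHalfFSC(imgs[, , selK, drop = FALSE],
                          as.matrix(ori[, c("phi", "theta", "psi")]),
                          as.matrix(ori[, c("sx", "sy")]), cf$voxelA)
      fscRes[as.character(k)] <- resolutionAtThreshold(fsc)
    }
    mapsF[[as.character(k)]] <- finalFilter(comp$maps[[k]],
      lowA = 20, highA = max(8.5, 2 * cf$voxelA), lowFreqFactor = 0.1)
    if (!is.null(cf$fitFree))
      fits[[as.character(k)]] <- hingeRefine(comp$maps[[k]],
        free = cf$fitFree, resolutionA = cf$resolutionA)
  }

  truth <- particleMeta(work)$state
  confusion <- table(truth, cls)
  mapping <- majorityMap(truth, cls)
  accuracy <- mean(mapping[as.character(cls)] == truth, na.rm = TRUE)

  recovered <- lapply(fits, function(f) f$params)
  contactTables <- lapply(fits, function(f)
    contactDistances(f$model, canonicalContacts()[
      canonicalContacts()$scope == "intersubunit", ]))
  contactStates <- lapply(contactTables, function(tb)
    assignStateFromContacts(tb)$state)

  report <- list(config = cf, confusion = confusion, accuracy = accuracy,
                 mapping = mapping, history = convergenceHistory(comp$partition),
                 fsc_resolution_A = fscRes, recovered = recovered,
                 contact_states = contactStates,
                 contact_tables = contactTables,
                 partition = comp$partition, orientations = comp$orientations,
                 junk = junk, eigen_selected = sel,
                 maps = comp$maps, maps_filtered = mapsF,
                 truth = truth)
  if (!is.null(cf$outdir)) writePipelineOutputs(report, work, cf$outdir)
  log_("done: accuracy ", sprintf("%.3f", accuracy))
  report
}

writePipelineOutputs <- function(report, stack, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeMRC(stack, file.path(outdir, "particles.mrc"))
  meta <- particleMeta(stack)
  meta$class <- classAssignment(report$partition)
  writeParticleMeta(meta, file.path(outdir, "particles.tsv"))
  for (k in seq_along(report$maps))
    writeMRC(report$maps[[k]], file.path(outdir, sprintf("class_%d.mrc", k)))
  for (nm in names(report$maps_filtered))
    writeMRC(report$maps_filtered[[nm]],
             file.path(outdir, sprintf("class_%s_filtered.mrc", nm)))
  for (nm in names(report$contact_tables))
    write.table(report$contact_tables[[nm]],
                file.path(outdir, sprintf("contacts_class_%s.tsv", nm)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  rep2 <- report[c("accuracy", "mapping", "history", "fsc_resolution_A",
                   "eigen_selected")]
  rep2$recovered <- report$recovered
  rep2$contact_states <- report$contact_states
  yaml::write_yaml(rep2, file.path(outdir, "report.yaml"))
  invisible(outdir)
}

#' Asymmetry validation of a class
#'
#' Reconstructs a class without imposing symmetry and compares the mean
#' density of the seven azimuthal wedges in the apical shell.  The null
#' distribution of the wedge variance under perfect C7 symmetry is built
#' by a symmetrised bootstrap (each particle's azimuth is shifted by a
#' random multiple of 360/7 and the reconstruction repeated); a class is
#' flagged when its observed wedge variance exceeds the null's 95th
#' percentile.  Used to vet competitive-alignment iterations for apical
#' heterogeneity hiding inside a "stable" class.
#'
#' @param images N x N x P array or [ParticleStack-class].
#' @param eulerDeg,shiftsPx,voxelA as in [reconstructC7()].
#' @param apicalZRangeA apical shell |z| band (Angstrom; the ATP ring is
#'   on +z).
#' @param radialRangeA radial band of the shell.
#' @param nBoot bootstrap replicates.
#' @param seed RNG seed.
#' @param nFoldSym symmetry order.
#' @return list: `wedgeMeans`, `variance`, `null`, `threshold95`,
#'   `flagged`, `elevatedWedges` (wedges more than 2 null SDs from the
#'   wedge mean).
#' @export
validateAsymmetric <- function(images, eulerDeg, shiftsPx = NULL,
                               voxelA = NULL, apicalZRangeA = c(48, 80),
                               radialRangeA = c(15, 48), nBoot = 20,
                               seed = 1, nFoldSym = 7) {
  if (is(images, "ParticleStack")) {
    if (is.null(voxelA)) voxelA <- images@pixelA
    images <- particleImages(images)
  }
  P <- dim(images)[3]
  if (P < nFoldSym) {
    warning("too few particles for an asymmetric reconstruction; skipped")
    return(NULL)
  }
  eulerDeg <- matrix(eulerDeg, ncol = 3)
  N <- dim(images)[1]
  x <- (seq_len(N) - 1 - N / 2) * voxelA
  X <- array(rep(x, times = N * N), c(N, N, N))
  Y <- array(rep(rep(x, each = N), times = N), c(N, N, N))
  Z <- array(rep(x, each = N * N), c(N, N, N))
  R <- sqrt(X^2 + Y^2)
  shell <- Z >= apicalZRangeA[1] & Z <= apicalZRangeA[2] &
    R >= radialRangeA[1] & R <= radialRangeA[2]
  wedge <- (floor((atan2(Y, X) / (2 * pi) * nFoldSym) %% nFoldSym)) + 1
  wedgeStats <- function(vol) {
    vapply(seq_len(nFoldSym), function(w)
      mean(vol[shell & wedge == w]), numeric(1))
  }
  obs <- wedgeStats(mapGrid(reconstructC7(images, eulerDeg, shiftsPx,
                                          voxelA, imposeSymmetry = FALSE)))
  set.seed(seed)
  null <- vapply(seq_len(nBoot), function(b) {
    ed <- eulerDeg
    ed[, 1] <- ed[, 1] + sample.int(nFoldSym, P, replace = TRUE) * 360 / nFoldSym
    var(wedgeStats(mapGrid(reconstructC7(images, ed, shiftsPx, voxelA,
                                         imposeSymmetry = FALSE))))
  }, numeric(1))
  thr <- quantile(null, 0.95)
  nullSD <- sqrt(mean(null))
  list(wedgeMeans = obs, variance = var(obs), null = null,
       threshold95 = unname(thr), flagged = var(obs) > thr,
       elevatedWedges = which(abs(obs - mean(obs)) > 2 * nullSD))
}
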