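# Deterministic rigid-body / hinge fitting of multi-domain models into
# density maps.  The optimisation is coordinate-wise: a coarse scan plus
# golden-section line search over each hinge parameter in tree order
# (equatorial -> intermediate+apical -> apical), repeated for a fixed
# number of sweeps; only improvements are accepted, so the
# cross-correlation is monotone non-decreasing by construction.  This
# replaces stochastic flexible-fitting machinery with a reproducible
# optimiser over the same rigid-group decomposition.

#' Real-space cross-correlation between a model and a map
#'
#' The model is rendered with the same Gaussian kernel as the phantom
#' density synthesis (no model/map kernel mismatch) and correlated with
#' the map over the voxels within `maskRadiusA` of any atom.
#'
#' @param model a [PhantomModel-class], or an n x 3 coordinate matrix.
#' @param map a [DensityMap-class].
#' @param maskRadiusA mask radius around atoms, Angstrom.
#' @param resolutionA rendering resolution (match the map's).
#' @param mass atom masses for bare coordinate input.
#' @return normalised cross-correlation in `[-1, 1]`.
#' @export
ccScore <- function(model, map, maskRadiusA = 8, resolutionA = 8, mass = 1) {
  if (is(model, "PhantomModel")) {
    coords <- atomCoords(model)
    mass <- model@atoms$mass
  } else coords <- model
  N <- boxSize(map)
  px <- voxelSize(map)
  if (max(abs(coords)) >= N * px / 2)
    stop("model extends outside the map")
  gc_ <- coords / px + N / 2
  mod <- cpp_synth_density(gc_, rep_len(mass, nrow(coords)), N,
                           sigmaForResolution(resolutionA) / px)
  msk <- cpp_atom_mask(gc_, N, maskRadiusA / px) > 0
  a <- mapGrid(map)[msk]
  b <- mod[msk]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Rigid 6-DOF docking of a model into a map
#'
#' Coarse grid search over z-rotations (one C-n asymmetric unit) and
#' small out-of-plane tilts, followed by local Nelder-Mead refinement of
#' all six degrees of freedom.  Deterministic.
#'
#' @param model a [PhantomModel-class] (or coordinates).
#' @param map a [DensityMap-class].
#' @param zStepDeg coarse z-rotation step.
#' @param tiltSetDeg coarse out-of-plane tilt offsets.
#' @param resolutionA,maskRadiusA scoring options (see [ccScore()]).
#' @param nFoldSym symmetry order bounding the z search.
#' @return list: `eulerDeg`, `translationA`, `cc`, `coords` (placed
#'   model coordinates), `failed` (TRUE when no positive-cc placement was
#'   found).
#' @export
rigidDock <- function(model, map, zStepDeg = 5, tiltSetDeg = c(-4, 0, 4),
                      resolutionA = 8, maskRadiusA = 8, nFoldSym = 7) {
  coords <- if (is(model, "PhantomModel")) atomCoords(model) else model
  mass <- if (is(model, "PhantomModel")) model@atoms$mass else 1
  place <- function(p) {
    R <- eulerMatrix(p[1:3])
    sweep(coords %*% t(R), 2, p[4:6], `+`)
  }
  score <- function(p) {
    co <- place(p)
    if (max(abs(co)) >= boxSize(map) * voxelSize(map) / 2) return(-2)
    cc <- ccScore(co, map, maskRadiusA, resolutionA, mass)
    if (is.na(cc)) -2 else cc
  }
  best <- NULL
  for (phi in seq(0, 360 / nFoldSym - 1e-9, by = zStepDeg))
    for (th in tiltSetDeg) {
      p <- c(phi, th, 0, 0, 0, 0)
      s <- score(p)
      if (is.null(best) || s > best$s) best <- list(p = p, s = s)
    }
  opt <- optim(best$p, function(p) -score(p), method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-8))
  p <- opt$par
  cc <- -opt$value
  list(eulerDeg = p[1:3], translationA = p[4:6], cc = cc,
       coords = place(p), failed = !is.finite(cc) || cc <= 0)
}

#' Rigid-group schedules for the hinge refinement
#'
#' Named presets mirroring the staged protocols used per state: the
#' closed ATP states refine the en-bloc tilt first and then all apical
#' hinge parameters; the open states free the radial expansion from the
#' start.
#'
#' @return named list of stage lists (each stage = parameter names).
#' @export
fitPresets <- function() {
  list(
    rs1 = list(c("tilt_deg"),
               c("tilt_deg", "elevation_deg", "twist_deg",
                 "equatorial_tilt_deg", "ring_rotation_deg")),
    rs2 = list(c("tilt_deg", "elevation_deg"),
               c("tilt_deg", "elevation_deg", "twist_deg",
                 "equatorial_tilt_deg", "ring_rotation_deg")),
    open = list(c("tilt_deg", "elevation_deg", "radial_shift_A"),
                c("tilt_deg", "elevation_deg", "radial_shift_A",
                  "twist_deg", "equatorial_tilt_deg", "ring_rotation_deg")),
    all = list(c("tilt_deg", "elevation_deg", "radial_shift_A",
                 "twist_deg", "equatorial_tilt_deg", "ring_rotation_deg"))
  )
}

defaultHingeBounds <- function() {
  list(tilt_deg = c(0, 60), elevation_deg = c(-10, 60),
       twist_deg = c(-30, 130), radial_shift_A = c(-4, 12),
       ring_rotation_deg = c(-10, 10), equatorial_tilt_deg = c(-5, 18))
}

#' Hinge-constrained refinement of a model against a map
#'
#' Starting from a docked model, optimises the hinge parameters of the
#' designated ring (each domain moved rigidly about its pivot) to
#' maximise the real-space cross-correlation with the map.  Each sweep
#' line-searches the free parameters in hinge-tree order (coarse scan,
#' then golden section); only improving moves are accepted, so the cc
#' history is monotone non-decreasing.  Values hitting a bound are
#' clamped and reported.
#'
#' @param map target [DensityMap-class].
#' @param startParams starting [stateParameters()] for the refined ring.
#' @param otherRing state of the unrefined ring.
#' @param free parameter names to refine, or a preset name from
#'   [fitPresets()] (stages are run in order, `nIter` sweeps each).
#' @param bounds named list of c(lo, hi) per parameter.
#' @param nIter sweeps per stage.
#' @param ring which ring is refined ("top").
#' @param subunit subunit template.
#' @param resolutionA,maskRadiusA scoring options.
#' @param tol line-search tolerance (degrees / Angstrom).
#' @return list: `params` (refined state), `cc`, `ccHistory` (per sweep),
#'   `iterations_used`, `clamped` (parameter names that hit a bound),
#'   `model` (refined [PhantomModel-class]).
#' @export
hingeRefine <- function(map, startParams = stateParameters("start"),
                        otherRing = "T", free = "all",
                        bounds = defaultHingeBounds(), nIter = 4,
                        ring = "top", subunit = defaultSubunit(),
                        resolutionA = 8, maskRadiusA = 8, tol = 0.05) {
  stages <- if (is.character(free) && length(free) == 1 &&
                free %in% names(fitPresets())) fitPresets()[[free]]
  else list(free)
  p <- startParams
  buildFor <- function(pp)
    if (ring == "top") buildStateModel(pp, otherRing, subunit = subunit)
    else buildStateModel(otherRing, pp, subunit = subunit)
  objective <- function(pp) {
    cc <- ccScore(buildFor(pp), map, maskRadiusA, resolutionA)
    if (is.na(cc)) -2 else cc
  }
  cc <- objective(p)
  ccHist <- numeric(0)
  clamped <- character(0)
  iters <- 0L
  for (stage in stages) {
    for (sweep in seq_len(nIter)) {
      iters <- iters + 1L
      for (par in stage) {
        b <- bounds[[par]]
        if (is.null(b)) stop("no bounds for parameter ", par)
        f1 <- function(x) {
          pp <- p
          pp[[par]] <- x
          objective(pp)
        }
        # coarse scan brackets the optimum, golden section polishes it
        xs <- seq(b[1], b[2], length.out = 13)
        vs <- vapply(xs, f1, numeric(1))
        i <- which.max(vs)
        lo <- xs[max(1, i - 1)]
        hi <- xs[min(length(xs), i + 1)]
        g <- goldenMax(f1, lo, hi, tol = tol)
        if (g$value > cc) {
          p[[par]] <- g$x
          cc <- g$value
          if (abs(g$x - b[1]) < tol || abs(g$x - b[2]) < tol)
            clamped <- union(clamped, par)
        }
      }
      ccHist <- c(ccHist, cc)
    }
  }
  list(params = p, cc = cc, ccHistory = ccHist, iterations_used = iters,
       clamped = clamped, model = buildFor(p))
}

#' Rebuild a C7 ring from one fitted subunit
#'
#' Replicates the fitted subunit's atoms by the n-fold rotation about z.
#' With `restoreLateralSheet` the lateral beta-sheet contact group is
#' snapped back to its reference geometry expressed in the fitted
#' equatorial frame (the construction used to guarantee the correct
#' intersubunit contact), then the ring is rebuilt.  A steric check
#' reports the minimum inter-subunit pseudo-atom distance.
#'
#' @param subunitCoords n x 3 coordinates of one fitted subunit (atom
#'   order of the template).
#' @param subunit the subunit template (for group labels and reference
#'   geometry).
#' @param restoreLateralSheet snap the lateral-sheet group back.
#' @param nFoldSym symmetry order.
#' @param stericFloorA distances below this are flagged.
#' @return list: `coords` ((n*nFold) x 3), `subunitCoords` (possibly
#'   sheet-restored), `minInterSubunitA`, `stericFlag`,
#'   `sheetRMSD` (RMSD of the restored group to reference geometry in the
#'   equatorial frame; 0 when restoration is off).
#' @export
rebuildRingC7 <- function(subunitCoords, subunit = defaultSubunit(),
                          restoreLateralSheet = FALSE, nFoldSym = 7,
                          stericFloorA = 1.0) {
  ref <- as.matrix(subunit$atoms[, c("x", "y", "z")])
  grp <- subunit$atoms$group
  dom <- subunit$atoms$domain
  sheet <- grp == "lateral_sheet"
  eq <- dom == "equatorial" & !sheet
  co <- subunitCoords
  sheetRMSD <- 0
  if (restoreLateralSheet) {
    # rigid transform of the reference equatorial core onto the fit
    k <- kabsch(ref[eq, , drop = FALSE], co[eq, , drop = FALSE])
    restored <- sweep(ref[sheet, , drop = FALSE] %*% t(k$R), 2, k$t, `+`)
    sheetRMSD <- sqrt(mean(rowSums((co[sheet, , drop = FALSE] - restored)^2)))
    co[sheet, ] <- restored
  }
  n <- nrow(co)
  all_co <- matrix(0, n * nFoldSym, 3)
  for (k in seq_len(nFoldSym))
    all_co[(k - 1) * n + seq_len(n), ] <- co %*% t(rotZ((k - 1) * 360 / nFoldSym))
  # steric check between adjacent subunits
  a <- all_co[seq_len(n), ]
  b <- all_co[n + seq_len(n), ]
  dmin <- min(sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), `+`) -
                         2 * a %*% t(b), 0)))
  list(coords = all_co, subunitCoords = co,
       minInterSubunitA = dmin, stericFlag = dmin < stericFloorA,
       sheetRMSD = sheetRMSD)
}
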