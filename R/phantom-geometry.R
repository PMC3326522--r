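# Ground-truth phantom geometry.
#
# The subunit is a coarse pseudo-atomic caricature -- three domain blobs
# (equatorial, intermediate, apical) with helix-like protrusions and
# designated marker pseudo-atoms for the residues whose intersubunit
# salt bridges fingerprint each allosteric state.  It is NOT a crystal
# structure: the point of the phantom is that the hinge kinematics and
# marker distances are exactly known, so classification, fitting and
# quantification can all be tested against truth.
#
# Local subunit frame: the subunit sits at azimuth 0 along +x, the ring
# symmetry axis is z, the top ring occupies z > 0.  The counterclockwise
# neighbour (subunit i+1) is at azimuth +360/7 degrees, i.e. towards +y.

# deterministic quasi-uniform directions (Fibonacci sphere)
fibDirections <- function(n) {
  i <- seq_len(n) - 0.5
  ph <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
}

# ellipsoidal blob of pseudo-atoms: centre point + two shells
blobPoints <- function(center, radii, n) {
  n_out <- ceiling(0.6 * n)
  n_in <- n - n_out - 1
  pts <- rbind(c(0, 0, 0),
               fibDirections(n_in) * 0.5,
               fibDirections(n_out) * 0.95)
  sweep(pts %*% diag(radii), 2, center, `+`)
}

linePoints <- function(from, to, n) {
  t <- seq(0, 1, length.out = n)
  cbind(from[1] + t * (to[1] - from[1]),
        from[2] + t * (to[2] - from[2]),
        from[3] + t * (to[3] - from[3]))
}

#' Default subunit geometry template
#'
#' Builds the canonical pseudo-atomic subunit: equatorial, intermediate and
#' apical domain blobs, helix-like protrusions (helices H, I, M and the K/L
#' hairpin), the lateral beta-sheet contact group on the equatorial domain,
#' the two hinge pivots, and the marker pseudo-atoms for all salt-bridge
#' residues.  Marker placement is calibrated so that the canonical state
#' library reproduces the published contact pattern switching (e.g. the
#' T-state R197-E386 bridge breaking on the 35 degree tilt and being
#' replaced by K80-E386) and the published D83-K327 separations.
#'
#' @return list with elements `atoms` (data.frame: x, y, z, mass, domain,
#'   group, label), `hinge1_point`, `hinge1_axis` (equatorial-intermediate
#'   pivot, radial axis), `hinge2_point`, `hinge2_axis`
#'   (intermediate-apical pivot, tangential axis), `eq_pivot`,
#'   `eq_axis` (inter-ring contact pivot for the equatorial tilt), and
#'   `markers` (named atom row indices).
#' @export
defaultSubunit <- function() {
  mk <- function(xyz, domain, group, label = NA_character_, mass = 1) {
    data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], mass = mass,
               domain = domain, group = group, label = label,
               stringsAsFactors = FALSE)
  }
  eq <- mk(blobPoints(c(33, 0, 14), c(10, 10, 11), 36), "equatorial", "blob")
  lat <- mk(linePoints(c(31, 11, 8), c(35, 12, 20), 5), "equatorial", "lateral_sheet")
  im <- mk(blobPoints(c(33, 0, 38), c(7, 8, 9), 16), "intermediate", "blob")
  hM <- mk(linePoints(c(29, -4, 30), c(29, -4, 44), 5), "intermediate", "helixM")
  ap <- mk(blobPoints(c(33, 0, 62), c(10, 10, 11), 26), "apical", "blob")
  hH <- mk(linePoints(c(24, 2, 56), c(18, 6, 62), 5), "apical", "helixH")
  hI <- mk(linePoints(c(24, 8, 58), c(27, 12, 57), 5), "apical", "helixI")
  hKL <- mk(linePoints(c(36, -2, 70), c(38, 2, 73), 4), "apical", "helixKL")

  # Marker pseudo-atoms, local frame (Angstrom).  Positions are calibrated
  # (numerically, against the canonical state library) so that the contact
  # truth table of the allosteric states holds with the 8 A cutoff and the
  # D83-K327 separation tracks the published 8 / 12.4 / 15.7 / 36 A values
  # over T / Rs1 / Rs_open / R_ES; see the methods vignette.
  markers <- rbind(
    mk(rbind(c(31.11, 12.86, 32.46)), "equatorial", "marker", "K80"),
    mk(rbind(c(27.14, 3.77, 31.60)), "equatorial", "marker", "D83"),
    mk(rbind(c(22, 5, 2)), "equatorial", "marker", "A109"),
    mk(rbind(c(42, 4, 3)), "equatorial", "marker", "R452"),
    mk(rbind(c(39.6, 11, -1)), "equatorial", "marker", "E461"),
    mk(rbind(c(42.5, 8.26, 1.2)), "equatorial", "marker", "V464"),
    mk(rbind(c(28.05, -6.08, 45.66)), "intermediate", "marker", "E386"),
    mk(rbind(c(26, 16, 50)), "apical", "marker", "R197"),
    mk(rbind(c(28, -10, 56)), "apical", "marker", "K207"),
    mk(rbind(c(12.35, -2.74, 63.26)), "apical", "marker", "K242"),
    mk(rbind(c(14.20, -0.98, 64.78)), "apical", "marker", "K245"),
    mk(rbind(c(27.00, 13.00, 58.00)), "apical", "marker", "E255"),
    mk(rbind(c(29.40, 14.83, 62.74)), "apical", "marker", "E257"),
    mk(rbind(c(27.26, -2.72, 36.34)), "apical", "marker", "K327")
  )
  atoms <- rbind(eq, lat, im, hM, ap, hH, hI, hKL, markers)
  rownames(atoms) <- NULL
  midx <- which(!is.na(atoms$label))
  names(midx) <- atoms$label[midx]
  list(atoms = atoms,
       hinge1_point = c(33, 0, 26), hinge1_axis = c(1, 0, 0),
       hinge2_point = c(33, 0, 50), hinge2_axis = c(0, 1, 0),
       eq_pivot = c(42, 5, 0), eq_axis = c(0, 1, 0),
       apical_center = c(33, 0, 62),
       markers = midx)
}

#' State parameters for one ring
#'
#' The hinge parameter set describing one ring's conformation.  All angles
#' in degrees, translations in Angstrom; the T state is all zero.
#' Transforms are applied in the fixed order tilt (hinge 1, radial axis)
#' -> elevation (hinge 2, tangential axis) -> radial shift -> twist (local
#' radial axis through the apical centre of mass); the equatorial tilt
#' pivots the equatorial domain about the inter-ring contact and the ring
#' rotation turns the whole ring about the symmetry axis.
#'
#' @param name state name.
#' @param tilt_deg rotation of the intermediate+apical block about hinge 1.
#' @param elevation_deg rotation of the apical domain about hinge 2.
#' @param twist_deg rotation of the apical domain about its local radial
#'   axis.
#' @param radial_shift_A outward translation of the apical domain.
#' @param ring_rotation_deg whole-ring rotation about the symmetry axis.
#' @param equatorial_tilt_deg equatorial pivot about the inter-ring contact.
#' @return list of class-free state parameters.
#' @export
stateParameters <- function(name = "custom", tilt_deg = 0, elevation_deg = 0,
                            twist_deg = 0, radial_shift_A = 0,
                            ring_rotation_deg = 0, equatorial_tilt_deg = 0) {
  list(name = name, tilt_deg = tilt_deg, elevation_deg = elevation_deg,
       twist_deg = twist_deg, radial_shift_A = radial_shift_A,
       ring_rotation_deg = ring_rotation_deg,
       equatorial_tilt_deg = equatorial_tilt_deg)
}

#' Canonical state library
#'
#' The per-ring parameter sets for the allosteric states: T (apo), the
#' single-ring ATP series Rs1 / Rs2 / Rs_open, the GroES-bound R_ES, and
#' the double-ring ATP series Rd1..Rd5 / Rd_open.  Published anchors: the
#' 35 degree en-bloc tilt (Rs1), the further 20 degree elevation from Rs2
#' to Rs_open, the ~100 degree clockwise twist to R_ES, and Rs_open at
#' about 70% of the R_ES elevation.  Values the study quotes only
#' qualitatively (Rs2 elevation, radial expansion, equatorial tilts, the
#' Rd ladder) are package defaults, flagged as stand-ins.
#'
#' @return named list of [stateParameters()] sets.
#' @export
canonicalStates <- function() {
  list(
    T = stateParameters("T"),
    Rs1 = stateParameters("Rs1", tilt_deg = 35,
                          equatorial_tilt_deg = 5.8, ring_rotation_deg = 2),
    Rs2 = stateParameters("Rs2", tilt_deg = 35, elevation_deg = 10,
                          equatorial_tilt_deg = 5.8, ring_rotation_deg = 2),
    Rs_open = stateParameters("Rs_open", tilt_deg = 35, elevation_deg = 30,
                              radial_shift_A = 5,
                              equatorial_tilt_deg = 12, ring_rotation_deg = 2),
    R_ES = stateParameters("R_ES", tilt_deg = 35, elevation_deg = 300 / 7,
                           twist_deg = 100, radial_shift_A = 5,
                           equatorial_tilt_deg = 12, ring_rotation_deg = 2),
    Rd1 = stateParameters("Rd1", tilt_deg = 24,
                          equatorial_tilt_deg = 6, ring_rotation_deg = 1),
    Rd3 = stateParameters("Rd3", tilt_deg = 25.5, elevation_deg = 1,
                          equatorial_tilt_deg = 6, ring_rotation_deg = 1),
    Rd2 = stateParameters("Rd2", tilt_deg = 29, elevation_deg = 2,
                          twist_deg = -4,
                          equatorial_tilt_deg = 8, ring_rotation_deg = 1),
    Rd4 = stateParameters("Rd4", tilt_deg = 32, elevation_deg = 3,
                          twist_deg = -8,
                          equatorial_tilt_deg = 10, ring_rotation_deg = 1),
    Rd5 = stateParameters("Rd5", tilt_deg = 32, elevation_deg = 16,
                          radial_shift_A = 4,
                          equatorial_tilt_deg = 12, ring_rotation_deg = 1),
    Rd_open = stateParameters("Rd_open", tilt_deg = 32, elevation_deg = 24,
                              radial_shift_A = 6,
                              equatorial_tilt_deg = 13, ring_rotation_deg = 1)
  )
}

resolveState <- function(state) {
  if (is.character(state)) {
    lib <- canonicalStates()
    if (!state %in% names(lib))
      stop("unknown state name '", state, "'; known: ",
           paste(names(lib), collapse = ", "))
    return(lib[[state]])
  }
  if (!is.list(state) || is.null(state$tilt_deg))
    stop("state must be a name or a stateParameters() list")
  state
}

# Apply one ring state to the subunit template; returns the transformed
# coordinate matrix (n x 3) in the local frame (no ring rotation --
# that is applied at assembly).
applyStateCoords <- function(sub, p) {
  for (ax in c("hinge1_axis", "hinge2_axis"))
    if (abs(sqrt(sum(sub[[ax]]^2)) - 1) > 1e-9)
      stop(ax, " must be unit length")
  co <- as.matrix(sub$atoms[, c("x", "y", "z")])
  dom <- sub$atoms$domain
  mov1 <- dom %in% c("intermediate", "apical")
  apil <- dom == "apical"
  eq <- dom == "equatorial"
  h2p <- sub$hinge2_point
  h2a <- sub$hinge2_axis
  rloc <- c(1, 0, 0)            # local radial axis, carried along
  # 1. en-bloc tilt of intermediate+apical about hinge 1
  if (p$tilt_deg != 0) {
    R1 <- axisAngleMatrix(sub$hinge1_axis, p$tilt_deg)
    co[mov1, ] <- rotateAbout(co[mov1, , drop = FALSE], sub$hinge1_point,
                              sub$hinge1_axis, p$tilt_deg)
    h2p <- as.numeric(R1 %*% (h2p - sub$hinge1_point)) + sub$hinge1_point
    h2a <- as.numeric(R1 %*% h2a)
    rloc <- as.numeric(R1 %*% rloc)
  }
  # 2. apical elevation about hinge 2
  if (p$elevation_deg != 0) {
    R2 <- axisAngleMatrix(h2a, p$elevation_deg)
    co[apil, ] <- rotateAbout(co[apil, , drop = FALSE], h2p, h2a,
                              p$elevation_deg)
    rloc <- as.numeric(R2 %*% rloc)
  }
  # 3. radial shift of the apical domain along the current local radial axis
  if (p$radial_shift_A != 0)
    co[apil, ] <- sweep(co[apil, , drop = FALSE], 2,
                        p$radial_shift_A * rloc, `+`)
  # 4. twist of the apical domain about its local radial axis through the
  # template's apical centre (carried through the preceding transforms)
  if (p$twist_deg != 0) {
    ctr <- sub$apical_center
    if (p$tilt_deg != 0)
      ctr <- as.numeric(axisAngleMatrix(sub$hinge1_axis, p$tilt_deg) %*%
                          (ctr - sub$hinge1_point)) + sub$hinge1_point
    if (p$elevation_deg != 0)
      ctr <- as.numeric(axisAngleMatrix(h2a, p$elevation_deg) %*%
                          (ctr - h2p)) + h2p
    ctr <- ctr + p$radial_shift_A * rloc
    co[apil, ] <- rotateAbout(co[apil, , drop = FALSE], ctr, rloc, p$twist_deg)
  }
  # equatorial pivot about the inter-ring contact
  if (p$equatorial_tilt_deg != 0)
    co[eq, ] <- rotateAbout(co[eq, , drop = FALSE], sub$eq_pivot, sub$eq_axis,
                            p$equatorial_tilt_deg)
  co
}

#' Build a double-ring phantom model
#'
#' Applies one ring state to each of the two rings and assembles the C7
#' double ring: the top ring's subunits at azimuths `k * 360/7` (plus the
#' ring rotation), the bottom ring flipped by the in-plane two-fold and
#' staggered by `ringStaggerDeg` so every subunit contacts two subunits of
#' the opposite ring.
#'
#' @param stateTop,stateBottom state names from [canonicalStates()] or
#'   [stateParameters()] lists.
#' @param subunit subunit template, from [defaultSubunit()].
#' @param nFoldSym symmetry order (7 for all canonical models).
#' @param ringStaggerDeg inter-ring stagger (default 360/14).
#' @param topOverrides,bottomOverrides optional named lists mapping subunit
#'   index ("1".."7") to a state, for planted-asymmetry experiments; using
#'   them marks the model as not C7 symmetric.
#' @return A [PhantomModel-class].
#' @examples
#' m <- buildStateModel("Rs1", "T")
#' nFold(m)
#' @export
buildStateModel <- function(stateTop, stateBottom = "T",
                            subunit = defaultSubunit(), nFoldSym = 7L,
                            ringStaggerDeg = 360 / 14,
                            topOverrides = list(), bottomOverrides = list()) {
  pTop <- resolveState(stateTop)
  pBot <- resolveState(stateBottom)
  symmetric <- length(topOverrides) == 0 && length(bottomOverrides) == 0
  flip <- diag(c(1, -1, -1))   # two-fold about x: maps top frame to bottom

  oneRing <- function(p, overrides, ringName) {
    pieces <- vector("list", nFoldSym)
    for (k in seq_len(nFoldSym)) {
      pk <- if (!is.null(overrides[[as.character(k)]]))
        resolveState(overrides[[as.character(k)]]) else p
      co <- applyStateCoords(subunit, pk)
      az <- (k - 1) * 360 / nFoldSym + pk$ring_rotation_deg
      if (ringName == "bottom") {
        co <- co %*% t(flip)
        az <- ringStaggerDeg + (k - 1) * 360 / nFoldSym - pk$ring_rotation_deg
      }
      co <- co %*% t(rotZ(az))
      df <- subunit$atoms
      df$x <- co[, 1]; df$y <- co[, 2]; df$z <- co[, 3]
      df$ring <- ringName
      df$subunit <- k
      pieces[[k]] <- df
    }
    do.call(rbind, pieces)
  }
  atoms <- rbind(oneRing(pTop, topOverrides, "top"),
                 oneRing(pBot, bottomOverrides, "bottom"))
  rownames(atoms) <- NULL
  new("PhantomModel", atoms = atoms, subunit = subunit,
      nFold = as.integer(nFoldSym), ringStaggerDeg = ringStaggerDeg,
      topState = pTop, bottomState = pBot, symmetric = symmetric)
}
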