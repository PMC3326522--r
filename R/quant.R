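# Quantification of domain motions and salt-bridge switching.
#
# Domain rotations are measured by least-squares rigid superposition
# (Kabsch) of the same domain's pseudo-atoms in two models, reported as
# axis / angle / translation; contact tables average marker-pair distances
# over the seven subunits, and a state's boolean contact pattern is
# matched against the published salt-bridge signatures.

#' Align two models into a common frame
#'
#' Two alignment conventions are provided.  `"superpose-free-ring"`
#' least-squares superposes the designated reference ring (for single-ATP
#' complexes, the nucleotide-free ring); `"z-rotation-by-com"` finds the
#' single rotation about the symmetry axis that best aligns the top-ring
#' subunit centres of mass (used for double-ATP complexes, where no free
#' ring exists).
#'
#' @param fitA,fitB [PhantomModel-class] objects sharing subunit topology.
#' @param mode "superpose-free-ring" or "z-rotation-by-com".
#' @param referenceRing which ring anchors mode 1 (default "bottom").
#' @return list with `a`, `b` (B transformed into A's frame), `R`, `t`,
#'   and for mode 2 the recovered `z_rotation_deg`.
#' @export
alignFrames <- function(fitA, fitB,
                        mode = c("superpose-free-ring", "z-rotation-by-com"),
                        referenceRing = "bottom") {
  mode <- match.arg(mode)
  if (nrow(fitA@atoms) != nrow(fitB@atoms))
    stop("models differ in subunit topology")
  if (mode == "superpose-free-ring") {
    a <- atomCoords(fitA, ring = referenceRing)
    b <- atomCoords(fitB, ring = referenceRing)
    k <- kabsch(b, a)        # transform B onto A
    atoms <- fitB@atoms
    co <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(k$R)
    co <- sweep(co, 2, k$t, `+`)
    atoms$x <- co[, 1]; atoms$y <- co[, 2]; atoms$z <- co[, 3]
    out <- fitB
    out@atoms <- atoms
    return(list(a = fitA, b = out, R = k$R, t = k$t, rmsd = k$rmsd))
  }
  # single z-rotation minimising top-ring subunit COM distances (closed form)
  comA <- t(vapply(seq_len(fitA@nFold), function(k)
    colMeans(atomCoords(fitA, ring = "top", subunit = k)), numeric(3)))
  comB <- t(vapply(seq_len(fitB@nFold), function(k)
    colMeans(atomCoords(fitB, ring = "top", subunit = k)), numeric(3)))
  num <- sum(comB[, 1] * comA[, 2] - comB[, 2] * comA[, 1])
  den <- sum(comB[, 1] * comA[, 1] + comB[, 2] * comA[, 2])
  ang <- atan2(num, den) * 180 / pi
  R <- rotZ(ang)
  atoms <- fitB@atoms
  co <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- co[, 1]; atoms$y <- co[, 2]; atoms$z <- co[, 3]
  out <- fitB
  out@atoms <- atoms
  list(a = fitA, b = out, R = R, t = c(0, 0, 0), z_rotation_deg = ang)
}

#' Measure the rigid motion of one domain between two models
#'
#' Least-squares superposition of the domain's pseudo-atoms from model A
#' onto model B, reported as rotation axis + angle, the residual
#' translation, and the centre-of-mass displacement.  Exact (to rounding)
#' for rigidly moved domains.
#'
#' @param fitA,fitB [PhantomModel-class] objects in a common frame.
#' @param domain "equatorial", "intermediate", "apical" or
#'   "intermediate+apical".
#' @param ring,subunit which copy to measure (default top ring, subunit 1).
#' @return list: `domain`, `angle_deg` in `[0, 180]`, unit `axis`,
#'   `translation_A`, `com_displacement_A`, `rmsd`.
#' @export
measureDomainMotion <- function(fitA, fitB, domain = "apical",
                                ring = "top", subunit = 1L) {
  doms <- if (domain == "intermediate+apical")
    c("intermediate", "apical") else domain
  a <- atomCoords(fitA, ring = ring, subunit = subunit, domain = doms)
  b <- atomCoords(fitB, ring = ring, subunit = subunit, domain = doms)
  if (nrow(a) < 3) stop("need at least 3 atoms in domain '", domain, "'")
  k <- kabsch(a, b)
  aa <- rotationAxisAngle(k$R)
  comA <- colMeans(a); comB <- colMeans(b)
  list(domain = domain, angle_deg = aa$angle_deg, axis = aa$axis,
       translation_A = comB - as.numeric(k$R %*% comA),
       com_displacement_A = sqrt(sum((comB - comA)^2)),
       rmsd = k$rmsd, R = k$R)
}

#' The published contact set
#'
#' The intersubunit salt bridges that fingerprint the allosteric states,
#' the intrasubunit D83-K327 pair, and the three inter-ring contacts.
#'
#' @return data.frame with columns a, b, kind, scope.
#' @export
canonicalContacts <- function() {
  data.frame(
    a = c("R197", "K80", "E255", "E255", "E257", "E257",
          "D83", "R452", "V464", "A109"),
    b = c("E386", "E386", "K207", "K245", "K245", "K242",
          "K327", "E461", "V464", "A109"),
    kind = c(rep("salt-bridge", 8), "van-der-Waals", "van-der-Waals"),
    scope = c(rep("intersubunit", 6), "intrasubunit", rep("interring", 3)),
    stringsAsFactors = FALSE)
}

markerAllCoords <- function(model, label, ring) {
  t(vapply(seq_len(model@nFold), function(k)
    markerCoords(model, label, ring = ring, subunit = k), numeric(3)))
}

#' Contact distance table
#'
#' For every contact definition, measures the marker-pair distance for each
#' of the seven subunit pairings and averages.  Intersubunit contacts pair
#' subunit i's residue `a` with the counterclockwise neighbour (i+1)'s
#' residue `b` (viewed from outside the top ring); inter-ring contacts use
#' the nearest staggered partner in the opposite ring; intrasubunit
#' contacts pair within each subunit.  A contact is flagged `in_contact`
#' when the mean distance is at or below the cutoff (the published
#' grey-out rule: contacts beyond 8 Angstrom are considered broken).
#'
#' @param model a [PhantomModel-class].
#' @param contacts contact definitions, default [canonicalContacts()].
#' @param cutoffA contact cutoff in Angstrom (default 8).
#' @param ring which ring's intersubunit contacts to measure.
#' @return data.frame: a, b, kind, scope, mean_A, sd_A, in_contact.
#' @export
contactDistances <- function(model, contacts = canonicalContacts(),
                             cutoffA = 8, ring = "top") {
  n <- model@nFold
  out <- contacts
  out$mean_A <- NA_real_
  out$sd_A <- NA_real_
  for (i in seq_len(nrow(contacts))) {
    ca <- contacts$a[i]; cb <- contacts$b[i]
    d <- switch(contacts$scope[i],
      intersubunit = {
        A <- markerAllCoords(model, ca, ring)
        B <- markerAllCoords(model, cb, ring)
        vapply(seq_len(n), function(k)
          sqrt(sum((A[k, ] - B[k %% n + 1, ])^2)), numeric(1))
      },
      intrasubunit = {
        A <- markerAllCoords(model, ca, ring)
        B <- markerAllCoords(model, cb, ring)
        sqrt(rowSums((A - B)^2))
      },
      interring = {
        A <- markerAllCoords(model, ca, "top")
        B <- markerAllCoords(model, cb, "bottom")
        vapply(seq_len(n), function(k) {
          dk <- sqrt(colSums((t(B) - A[k, ])^2))
          min(dk)
        }, numeric(1))
      },
      stop("unknown scope: ", contacts$scope[i]))
    out$mean_A[i] <- mean(d)
    out$sd_A[i] <- sd(d)
  }
  out$in_contact <- out$mean_A <= cutoffA
  out
}

#' Inter-ring contact length changes between two models
#'
#' Measures the three inter-ring contact distances (R452-E461, V464-V464,
#' A109-A109) in each model and returns their change (B minus A); the
#' published signature of negative inter-ring cooperativity is the ~2 A
#' lengthening of the A109-A109 contact on ATP binding.
#'
#' @param modelA,modelB [PhantomModel-class] double-ring models.
#' @return data.frame: contact, mean_A_a, mean_A_b, change_A.
#' @export
interringMetrics <- function(modelA, modelB) {
  cc <- canonicalContacts()
  cc <- cc[cc$scope == "interring", ]
  ta <- contactDistances(modelA, cc)
  tb <- contactDistances(modelB, cc)
  data.frame(contact = paste(cc$a, cc$b, sep = "-"),
             mean_A_a = ta$mean_A, mean_A_b = tb$mean_A,
             change_A = tb$mean_A - ta$mean_A)
}

#' Salt-bridge signatures of the allosteric states
#'
#' The boolean in-contact pattern over the six intersubunit salt bridges
#' that defines each state: T holds R197-E386 and E255-K207; Rs1/Rs2 hold
#' K80-E386 and E255-K245 (distinguished by elevation, not contacts); the
#' double-ATP ladder slips from 255-245 (Rd1/Rd3) to 255/257-245 (Rd2) to
#' 255/257-245/242 (Rd4); the open states have no apical intersubunit
#' contacts.
#'
#' @return logical matrix, states x contacts.
#' @export
stateSignatures <- function() {
  keys <- c("R197-E386", "K80-E386", "E255-K207",
            "E255-K245", "E257-K245", "E257-K242")
  sig <- rbind(
    T = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    Rs1 = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    Rs2 = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    Rd1 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    Rd3 = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    Rd2 = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    Rd4 = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    `R-open` = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  colnames(sig) <- keys
  sig
}

#' Assign a state label from a contact table
#'
#' Nearest-pattern (Hamming) match of the boolean in-contact vector
#' against the state signature table.  States sharing a signature (Rs1/Rs2,
#' Rd1/Rd3, and the open family) are returned as a tied set; the
#' confidence is the Hamming margin between the best and the runner-up
#' signature.
#'
#' @param table a contact table from [contactDistances()] covering the six
#'   intersubunit salt bridges.
#' @return list: `state` (character vector; length > 1 on ties),
#'   `margin` (integer Hamming margin), `distances` per signature.
#' @export
assignStateFromContacts <- function(table) {
  sig <- stateSignatures()
  key <- paste(table$a, table$b, sep = "-")
  v <- setNames(table$in_contact, key)
  miss <- setdiff(colnames(sig), key)
  if (length(miss))
    stop("contact table misses: ", paste(miss, collapse = ", "))
  v <- v[colnames(sig)]
  d <- apply(sig, 1, function(s) sum(s != v))
  dm <- sort(unique(d))
  best <- names(d)[d == dm[1]]
  # collapse label groups that share one signature
  margin <- if (length(dm) > 1) dm[2] - dm[1] else 0L
  if (setequal(best, c("Rs1", "Rs2"))) best <- c("Rs1", "Rs2")
  if (identical(sort(best), "R-open")) best <- "R-open family"
  list(state = best, margin = as.integer(margin), distances = d)
}
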