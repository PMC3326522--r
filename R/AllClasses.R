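#' DensityMap: a cubic 3D scalar grid
#'
#' The unit of reconstruction, filtering and fitting.  The grid is cubic,
#' `voxelA` gives the sampling in Angstrom per voxel, and `originA` is the
#' position (Angstrom) of the voxel with 0-based index (0,0,0); the
#' geometric centre of the grid (0-based index N/2) sits at coordinate 0.
#'
#' @slot grid 3D numeric array, cubic.
#' @slot voxelA numeric(1), Angstrom per voxel, positive.
#' @slot originA numeric(3), Angstrom.
#' @export
setClass("DensityMap",
  representation(grid = "array", voxelA = "numeric", originA = "numeric"),
  validity = function(object) {
    d <- dim(object@grid)
    if (length(d) != 3L || length(unique(d)) != 1L)
      return("grid must be a cubic 3D array")
    if (length(object@voxelA) != 1L || object@voxelA <= 0)
      return("voxelA must be a single positive number")
    if (length(object@originA) != 3L)
      return("originA must have length 3")
    TRUE
  })

#' Construct a DensityMap
#'
#' @param grid cubic 3D numeric array.
#' @param voxelA voxel size in Angstrom.
#' @param originA origin in Angstrom; defaults to centring the grid on 0.
#' @return A [DensityMap-class] object.
#' @export
DensityMap <- function(grid, voxelA, originA = rep(-voxelA * (dim(grid)[1] %/% 2), 3)) {
  new("DensityMap", grid = grid, voxelA = voxelA, originA = as.numeric(originA))
}

#' @describeIn DensityMap-class grid side length in voxels.
#' @param x,object a `DensityMap`.
#' @export
setGeneric("boxSize", function(x) standardGeneric("boxSize"))
#' @rdname DensityMap-class
#' @export
setMethod("boxSize", "DensityMap", function(x) dim(x@grid)[1])

#' @describeIn DensityMap-class voxel size in Angstrom.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname DensityMap-class
#' @export
setMethod("voxelSize", "DensityMap", function(x) x@voxelA)

#' @describeIn DensityMap-class the raw 3D array.
#' @export
setGeneric("mapGrid", function(x) standardGeneric("mapGrid"))
#' @rdname DensityMap-class
#' @export
setMethod("mapGrid", "DensityMap", function(x) x@grid)

setMethod("show", "DensityMap", function(object) {
  n <- boxSize(object)
  cat(sprintf("DensityMap: %d^3 voxels, %.3f A/voxel (box %.1f A)\n",
              n, object@voxelA, n * object@voxelA))
  cat(sprintf("  density range [%.4g, %.4g]\n",
              min(object@grid), max(object@grid)))
})

#' ParticleStack: a 2D image stack with per-particle metadata
#'
#' Images are square and stored as an N x N x P array.  The metadata table
#' carries one row per particle; simulated stacks record the ground truth
#' (state, Euler angles, shifts, defocus) and processing stages append
#' alignment results.
#'
#' @slot images numeric array N x N x P.
#' @slot pixelA numeric(1), Angstrom per pixel.
#' @slot meta data.frame with P rows.
#' @export
setClass("ParticleStack",
  representation(images = "array", pixelA = "numeric", meta = "data.frame"),
  validity = function(object) {
    d <- dim(object@images)
    if (length(d) != 3L || d[1] != d[2])
      return("images must be an N x N x P array")
    if (nrow(object@meta) != d[3])
      return("meta must have one row per particle")
    if (object@pixelA <= 0) return("pixelA must be positive")
    TRUE
  })

#' Construct a ParticleStack
#' @param images N x N x P array.
#' @param pixelA pixel size in Angstrom.
#' @param meta data.frame with one row per particle.
#' @return A [ParticleStack-class] object.
#' @export
ParticleStack <- function(images, pixelA,
                          meta = data.frame(index = seq_len(dim(images)[3]))) {
  new("ParticleStack", images = images, pixelA = pixelA, meta = meta)
}

#' @describeIn ParticleStack-class number of particles.
#' @param x,object a `ParticleStack`.
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))
#' @rdname ParticleStack-class
#' @export
setMethod("nParticles", "ParticleStack", function(x) dim(x@images)[3])

#' @describeIn ParticleStack-class per-particle metadata.
#' @export
setGeneric("particleMeta", function(x) standardGeneric("particleMeta"))
#' @rdname ParticleStack-class
#' @export
setMethod("particleMeta", "ParticleStack", function(x) x@meta)

#' @describeIn ParticleStack-class the raw image array.
#' @export
setGeneric("particleImages", function(x) standardGeneric("particleImages"))
#' @rdname ParticleStack-class
#' @export
setMethod("particleImages", "ParticleStack", function(x) x@images)

setMethod("show", "ParticleStack", function(object) {
  d <- dim(object@images)
  cat(sprintf("ParticleStack: %d particles, %dx%d px at %.3f A/px\n",
              d[3], d[1], d[2], object@pixelA))
  if ("state" %in% names(object@meta))
    print(table(object@meta$state))
})

#' ClassPartition: an assignment of particles to conformational classes
#'
#' @slot assignment integer vector; class id per particle, 0 marks the junk
#'   class.
#' @slot history numeric; per-iteration fraction of particles that changed
#'   class (empty for single-pass partitions).
#' @slot classSizes integer; particles per class.
#' @export
setClass("ClassPartition",
  representation(assignment = "integer", history = "numeric",
                 classSizes = "integer"),
  validity = function(object) {
    if (any(object@assignment < 0L))
      return("assignment ids must be >= 0 (0 = junk)")
    if (length(object@history) && (any(object@history < 0) || any(object@history > 1)))
      return("history fractions must lie in [0, 1]")
    TRUE
  })

#' Construct a ClassPartition
#' @param assignment integer class ids (0 = junk).
#' @param history per-iteration moved fractions.
#' @return A [ClassPartition-class] object.
#' @export
ClassPartition <- function(assignment, history = numeric(0)) {
  assignment <- as.integer(assignment)
  ids <- sort(unique(assignment[assignment > 0L]))
  sizes <- vapply(ids, function(i) sum(assignment == i), integer(1))
  names(sizes) <- ids
  new("ClassPartition", assignment = assignment, history = as.numeric(history),
      classSizes = sizes)
}

#' @describeIn ClassPartition-class class id per particle.
#' @param x,object a `ClassPartition`.
#' @export
setGeneric("classAssignment", function(x) standardGeneric("classAssignment"))
#' @rdname ClassPartition-class
#' @export
setMethod("classAssignment", "ClassPartition", function(x) x@assignment)

#' @describeIn ClassPartition-class per-iteration moved fraction.
#' @export
setGeneric("convergenceHistory", function(x) standardGeneric("convergenceHistory"))
#' @rdname ClassPartition-class
#' @export
setMethod("convergenceHistory", "ClassPartition", function(x) x@history)

setMethod("show", "ClassPartition", function(object) {
  cat("ClassPartition:", length(object@assignment), "particles in",
      length(object@classSizes), "classes")
  nj <- sum(object@assignment == 0L)
  if (nj) cat(" (+", nj, "junk)")
  cat("\n  sizes:", paste(object@classSizes, collapse = ", "), "\n")
  if (length(object@history))
    cat("  moved fraction per iteration:",
        paste(sprintf("%.3f", object@history), collapse = ", "), "\n")
})

#' EigenDecomposition: eigenimages of an aligned stack
#'
#' Principal components of the pixel covariance of an aligned image stack;
#' the classical route to detecting conformational heterogeneity.
#'
#' @slot meanImage the average image.
#' @slot components N x N x k array of unit-norm eigenimages.
#' @slot eigenvalues non-negative, non-increasing variances.
#' @export
setClass("EigenDecomposition",
  representation(meanImage = "matrix", components = "array",
                 eigenvalues = "numeric"),
  validity = function(object) {
    if (any(diff(object@eigenvalues) > 1e-8))
      return("eigenvalues must be non-increasing")
    if (any(object@eigenvalues < -1e-8))
      return("eigenvalues must be non-negative")
    TRUE
  })

setMethod("show", "EigenDecomposition", function(object) {
  k <- length(object@eigenvalues)
  cat(sprintf("EigenDecomposition: %d components of %dx%d images\n",
              k, nrow(object@meanImage), ncol(object@meanImage)))
  cat("  leading eigenvalues:",
      paste(sprintf("%.3g", head(object@eigenvalues, 5)), collapse = ", "), "\n")
})

#' FSCCurve: Fourier shell correlation between two half-maps
#'
#' @slot shellFreq spatial frequency (1/Angstrom) per shell, increasing.
#' @slot correlation FSC value per shell.
#' @slot threshold the resolution criterion (0.5 here).
#' @export
setClass("FSCCurve",
  representation(shellFreq = "numeric", correlation = "numeric",
                 threshold = "numeric"),
  validity = function(object) {
    if (length(object@shellFreq) != length(object@correlation))
      return("shellFreq and correlation lengths differ")
    if (any(diff(object@shellFreq) <= 0))
      return("shell frequencies must be strictly increasing")
    TRUE
  })

setMethod("show", "FSCCurve", function(object) {
  cat(sprintf("FSCCurve: %d shells to %.3g 1/A\n",
              length(object@shellFreq), max(object@shellFreq)))
  r <- resolutionAtThreshold(object)
  cat(sprintf("  resolution at FSC=%.2f: %.2f A\n", object@threshold, r))
})

#' PhantomModel: pseudo-atomic double-ring ground-truth model
#'
#' A coarse pseudo-atomic caricature of the double-ring complex: per
#' subunit, three domain blobs (equatorial, intermediate, apical) with
#' helix-like protrusions and designated marker pseudo-atoms for the
#' salt-bridge residues, replicated with C7 symmetry into two staggered
#' rings.  The hinge parameters of each ring's state are exactly known, so
#' every downstream measurement can be tested against truth.
#'
#' @slot atoms data.frame with columns x, y, z (Angstrom), mass, ring
#'   ("top"/"bottom"), subunit (1..7), domain, group, label.
#' @slot subunit the subunit geometry template (see [defaultSubunit()]).
#' @slot nFold integer symmetry order (7 for all canonical models).
#' @slot ringStaggerDeg inter-ring rotational offset in degrees.
#' @slot topState,bottomState state parameter lists (see [stateParameters()]).
#' @slot symmetric TRUE unless per-subunit overrides broke the C7 symmetry.
#' @export
setClass("PhantomModel",
  representation(atoms = "data.frame", subunit = "list", nFold = "integer",
                 ringStaggerDeg = "numeric", topState = "list",
                 bottomState = "list", symmetric = "logical"),
  validity = function(object) {
    need <- c("x", "y", "z", "mass", "ring", "subunit", "domain", "group", "label")
    if (!all(need %in% names(object@atoms)))
      return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (object@nFold < 1L) return("nFold must be >= 1")
    if (object@symmetric && object@nFold > 1L) {
      # C7 closure: rotating subunit k's atoms by 360/n reproduces k+1
      a <- object@atoms
      s1 <- a[a$ring == "top" & a$subunit == 1L, c("x", "y", "z")]
      s2 <- a[a$ring == "top" & a$subunit == 2L, c("x", "y", "z")]
      th <- 2 * pi / object@nFold
      rot <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
      err <- max(abs(as.matrix(s1) %*% t(rot) - as.matrix(s2)))
      if (err > 1e-6) return(sprintf("C7 closure violated (%.2g A)", err))
    }
    TRUE
  })

#' @describeIn PhantomModel-class symmetry order.
#' @param x,object a `PhantomModel`.
#' @export
setGeneric("nFold", function(x) standardGeneric("nFold"))
#' @rdname PhantomModel-class
#' @export
setMethod("nFold", "PhantomModel", function(x) x@nFold)

#' @describeIn PhantomModel-class atom coordinate matrix (n x 3, Angstrom),
#'   optionally restricted by ring / subunit / domain.
#' @param ring,subunit,domain optional filters.
#' @export
setGeneric("atomCoords", function(x, ring = NULL, subunit = NULL, domain = NULL)
  standardGeneric("atomCoords"))
#' @rdname PhantomModel-class
#' @export
setMethod("atomCoords", "PhantomModel", function(x, ring = NULL, subunit = NULL,
                                                 domain = NULL) {
  a <- x@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(ring)) keep <- keep & a$ring %in% ring
  if (!is.null(subunit)) keep <- keep & a$subunit %in% subunit
  if (!is.null(domain)) keep <- keep & a$domain %in% domain
  as.matrix(a[keep, c("x", "y", "z")])
})

#' @describeIn PhantomModel-class coordinates of a named marker pseudo-atom.
#' @param label marker label, e.g. "E386".
#' @export
setGeneric("markerCoords", function(x, label, ring = "top", subunit = 1L)
  standardGeneric("markerCoords"))
#' @rdname PhantomModel-class
#' @export
setMethod("markerCoords", "PhantomModel", function(x, label, ring = "top",
                                                   subunit = 1L) {
  a <- x@atoms
  hit <- !is.na(a$label) & a$label == label & a$ring == ring &
    a$subunit == subunit
  if (!any(hit)) stop("no marker '", label, "' in ", ring, " subunit ", subunit)
  unname(as.numeric(a[hit, c("x", "y", "z")][1, ]))
})

setMethod("show", "PhantomModel", function(object) {
  cat(sprintf("PhantomModel: C%d double ring, %d pseudo-atoms\n",
              object@nFold, nrow(object@atoms)))
  cat(sprintf("  top ring state: %s | bottom ring state: %s\n",
              object@topState$name, object@bottomState$name))
  if (!object@symmetric) cat("  (per-subunit overrides: not C7 symmetric)\n")
})
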