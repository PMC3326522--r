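# MRC map/stack I/O (mode 2, little-endian) and plain-text side formats.
# The MRC reader/writer is deliberately minimal: cubic maps and square
# image stacks with correct voxel-size headers, which is all the pipeline
# emits and consumes.

#' Write a density map or particle stack as MRC (mode 2)
#'
#' @param x a [DensityMap-class], [ParticleStack-class], 3D array or
#'   matrix.
#' @param file output path.
#' @param voxelA voxel size (taken from the object when available).
#' @return `file`, invisibly.
#' @export
writeMRC <- function(x, file, voxelA = NULL) {
  if (is(x, "DensityMap")) { data <- mapGrid(x); voxelA <- voxelSize(x) }
  else if (is(x, "ParticleStack")) { data <- particleImages(x); voxelA <- x@pixelA }
  else data <- x
  if (is.null(voxelA)) stop("voxelA required for bare arrays")
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  d <- dim(data)
  con <- file(file, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2: float32
  wi(c(0, 0, 0))              # nxstart
  wi(d)                       # mx my mz
  wf(d * voxelA)              # cella
  wf(c(90, 90, 90))           # cellb
  wi(c(1, 2, 3))              # mapc mapr maps
  wf(c(min(data), max(data), mean(data)))
  wi(0)                       # ispg
  wi(0)                       # nsymbt
  wi(rep(0, 25))              # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)   # little-endian stamp
  wf(sd(as.numeric(data)))
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(file)
}

#' Read an MRC file
#'
#' @param file path to an MRC file (mode 0/1/2).
#' @return list with `data` (array), `voxelA`, `dim`.
#' @export
readMRC <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  ri(3); mxyz <- ri(3)
  cella <- rf(3); rf(3); ri(3); rf(3); ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  n <- prod(d)
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n, size = 1, endian = "little"),
    "1" = readBin(con, "integer", n, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    stop("unsupported MRC mode: ", mode))
  list(data = array(as.numeric(data), d),
       voxelA = if (mxyz[1] > 0) cella[1] / mxyz[1] else NA_real_,
       dim = d)
}

#' Read an MRC volume as a DensityMap
#' @param file path to a cubic MRC volume.
#' @return A [DensityMap-class].
#' @export
readMRCMap <- function(file) {
  m <- readMRC(file)
  DensityMap(m$data, m$voxelA)
}

#' Write / read a particle metadata table (tab-separated)
#'
#' One row per particle: index, state, Euler angles, shifts, defocus and
#' seed, plus any processing columns appended downstream.
#'
#' @param meta data.frame (or a [ParticleStack-class], whose metadata is
#'   taken).
#' @param file path.
#' @return `file` invisibly / the data.frame.
#' @export
writeParticleMeta <- function(meta, file) {
  if (is(meta, "ParticleStack")) meta <- particleMeta(meta)
  write.table(meta, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeParticleMeta
#' @export
readParticleMeta <- function(file) {
  hdr <- names(read.table(file, header = TRUE, sep = "\t", nrows = 1))
  cc <- ifelse(hdr %in% c("state", "ring", "domain", "group", "label"),
               "character", NA)
  read.table(file, header = TRUE, sep = "\t", colClasses = cc,
             stringsAsFactors = FALSE)
}

#' Write a phantom model in PDB format
#'
#' Chains encode the ring/subunit (top ring A-G, bottom ring H-N); the
#' segment id carries the rigid-group name and marker pseudo-atoms keep
#' their residue label in the residue-number field.
#'
#' @param model a [PhantomModel-class].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeModelPDB <- function(model, file) {
  a <- model@atoms
  chains <- c(LETTERS[1:7], LETTERS[8:14])
  ch <- ifelse(a$ring == "top", chains[a$subunit], chains[7 + a$subunit])
  resno <- ifelse(is.na(a$label), seq_len(nrow(a)) %% 9999,
                  as.integer(sub("^[A-Z]+", "", a$label)))
  n <- nrow(a)
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = resno, chain = ch,
                   resid = ifelse(is.na(a$label), "GLY", "MRK"),
                   elety = rep("CA", n), o = a$mass,
                   segid = substr(a$group, 1, 4))
  invisible(file)
}

#' Read pseudo-atom coordinates from a PDB file
#'
#' The optional import path for fitting real (or previously written)
#' coordinates: returns the coordinate matrix and per-atom chain ids.
#'
#' @param file PDB path.
#' @param elety atom name filter (default CA).
#' @return list: `coords` (n x 3), `chain`, `resno`.
#' @export
readCoordsPDB <- function(file, elety = "CA") {
  pdb <- bio3d::read.pdb(file)
  sel <- bio3d::atom.select(pdb, elety = elety, verbose = FALSE)
  at <- pdb$atom[sel$atom, ]
  list(coords = as.matrix(at[, c("x", "y", "z")]),
       chain = at$chain, resno = at$resno)
}
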