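# Rotation and superposition helpers shared by all modules.
# Euler convention (declared once, used everywhere): ZYZ, intrinsic,
# degrees; R = Rz(phi) %*% Ry(theta) %*% Rz(psi).  The in-plane rotation
# of a projection is the final Z angle psi.

deg2rad <- function(x) x * pi / 180

rotZ <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rotY <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' ZYZ intrinsic Euler rotation matrix
#'
#' @param eulerDeg numeric(3): phi (azimuth), theta (tilt), psi (in-plane),
#'   degrees.
#' @return 3x3 rotation matrix `Rz(phi) Ry(theta) Rz(psi)`.
#' @export
eulerMatrix <- function(eulerDeg) {
  rotZ(eulerDeg[1]) %*% rotY(eulerDeg[2]) %*% rotZ(eulerDeg[3])
}

#' Axis-angle rotation matrix (Rodrigues)
#'
#' @param axis numeric(3); normalised internally.
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
axisAngleMatrix <- function(axis, deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  u <- axis / n
  a <- deg2rad(deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# rotate points (n x 3) about an axis through a pivot point
rotateAbout <- function(pts, pivot, axis, deg) {
  if (abs(deg) < 1e-300) return(pts)
  R <- axisAngleMatrix(axis, deg)
  sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, `+`)
}

#' Axis and angle of a rotation matrix
#'
#' @param R 3x3 rotation matrix.
#' @return list with `angle_deg` in `[0, 180]` and unit `axis` (arbitrary
#'   for the identity).
#' @export
rotationAxisAngle <- function(R) {
  ca <- max(-1, min(1, (sum(diag(R)) - 1) / 2))
  ang <- acos(ca)
  if (ang < 1e-12) return(list(angle_deg = 0, axis = c(0, 0, 1)))
  if (pi - ang < 1e-6) {
    # angle ~ 180: axis from the symmetric part
    B <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonals
    i <- which.max(ax)
    if (i == 1) ax <- c(ax[1], B[1, 2] / ax[1], B[1, 3] / ax[1])
    if (i == 2) ax <- c(B[1, 2] / ax[2], ax[2], B[2, 3] / ax[2])
    if (i == 3) ax <- c(B[1, 3] / ax[3], B[2, 3] / ax[3], ax[3])
    ax <- ax / sqrt(sum(ax^2))
    return(list(angle_deg = 180, axis = ax))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  list(angle_deg = ang * 180 / pi, axis = ax / sqrt(sum(ax^2)))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation `R` and translation `t` minimising
#' `sum || R a_i + t - b_i ||^2`.
#'
#' @param a,b n x 3 coordinate matrices in correspondence.
#' @return list with `R` (3x3), `t` (3), `rmsd`.
#' @export
kabsch <- function(a, b) {
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in size")
  if (nrow(a) < 3) stop("need at least 3 points")
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  fit <- sweep(A %*% t(R), 2, cb, `+`)
  rmsd <- sqrt(mean(rowSums((fit - sweep(B, 2, cb, `+`))^2)))
  list(R = R, t = t, rmsd = rmsd)
}

# golden-section maximisation of f on [lo, hi]
goldenMax <- function(f, lo, hi, tol = 0.02) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  x <- if (f1 > f2) x1 else x2
  list(x = x, value = max(f1, f2))
}
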