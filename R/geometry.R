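## Low-level vector geometry shared by all modules.  Coordinates are plain
## numeric 3-vectors or n x 3 matrices, lengths in Angstrom, angles in degrees
## unless a function says otherwise.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## signed angle (degrees) from a to b about axis n
signed_angle <- function(a, b, n) {
  a <- unitv(a); b <- unitv(b); n <- unitv(n)
  s <- sum(cross3(a, b) * n)
  c0 <- sum(a * b)
  atan2(s, c0) / DEG
}

vec_angle <- function(a, b) {
  acos(max(-1, min(1, sum(unitv(a) * unitv(b))))) / DEG
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (need not be unit length).
#' @param theta angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rot_axis <- function(axis, theta) {
  u <- unitv(axis)
  th <- theta * DEG
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

rot_x <- function(theta) rot_axis(c(1, 0, 0), theta)
rot_y <- function(theta) rot_axis(c(0, 1, 0), theta)
rot_z <- function(theta) rot_axis(c(0, 0, 1), theta)

## axis and angle (degrees) of a proper rotation matrix
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  ct <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(ct)
  if (theta < 1e-9) {
    return(list(axis = c(0, 0, 1), angle = 0))
  }
  if (abs(theta - pi) < 1e-6) {
    ## near 180 deg: axis from the symmetric part
    B <- (R + diag(3L)) / 2
    ax <- sqrt(pmax(diag(B), 0))
    k <- which.max(ax)
    ax <- B[, k] / ax[k]
    return(list(axis = unitv(ax), angle = theta / DEG))
  }
  ax <- c(R[3L, 2L] - R[2L, 3L], R[1L, 3L] - R[3L, 1L], R[2L, 1L] - R[1L, 2L])
  list(axis = unitv(ax), angle = theta / DEG)
}

## nearest proper rotation to an arbitrary 3x3 matrix (via SVD)
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Dihedral (torsion) angle of four points
#'
#' IUPAC sign convention: looking from p2 to p3, clockwise rotation of the
#' far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return torsion in degrees, in (-180, 180].
#' @keywords internal
torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  -atan2(y, x) / DEG
}

#' Least-squares superposition of two point sets
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% reference + t` against `mobile` (Kabsch algorithm with a
#' determinant constraint, so mirror images are never produced).
#'
#' @param reference n x 3 matrix of reference coordinates (n >= 3).
#' @param mobile n x 3 matrix of corresponding target coordinates.
#' @return list with `rotation` (3x3, det +1), `translation` (3-vector) and
#'   `rmsd` (Angstrom).
#' @examples
#' pts <- matrix(rnorm(12), 4, 3)
#' fit <- superpose(pts, pts)
#' fit$rmsd  # 0
#' @export
superpose <- function(reference, mobile) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  if (nrow(reference) != nrow(mobile) || ncol(reference) != 3L ||
      ncol(mobile) != 3L) {
    stop("superpose needs two n x 3 matrices of corresponding points")
  }
  n <- nrow(reference)
  if (n < 3L) stop("degenerate fit: need at least 3 corresponding points")
  cr <- colMeans(reference); cm <- colMeans(mobile)
  A <- sweep(reference, 2L, cr); B <- sweep(mobile, 2L, cm)
  ## collinearity check on the reference
  if (qr(A)$rank < 2L || qr(B)$rank < 2L) {
    stop("degenerate fit: points are collinear")
  }
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t_vec <- unname(cm - as.vector(R %*% cr))
  fitted <- t(R %*% t(reference)) + matrix(t_vec, n, 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - mobile)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

## apply a rigid transform to an n x 3 matrix
apply_transform <- function(xyz, R, t) {
  sweep(t(R %*% t(as.matrix(xyz))), 2L, -as.numeric(t))
}

## best-fit 3D line through points; returns point on line and unit direction
fit_line3 <- function(pts) {
  pts <- as.matrix(pts)
  ctr <- colMeans(pts)
  if (nrow(pts) < 2L) return(list(point = ctr, dir = c(0, 0, 1)))
  X <- sweep(pts, 2L, ctr)
  sv <- svd(X)
  dir <- sv$v[, 1L]
  if (dir[3L] < 0) dir <- -dir
  list(point = ctr, dir = unitv(dir))
}

point_line_distance <- function(p, line) {
  d <- p - line$point
  vnorm(d - sum(d * line$dir) * line$dir)
}

## distance from point p to the (infinite) line through a and b
point_segment_line_distance <- function(p, a, b) {
  u <- unitv(b - a)
  d <- p - a
  vnorm(d - sum(d * u) * u)
}
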