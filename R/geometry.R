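## ---- small 3-D geometry toolkit used throughout the package ----

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  a / n
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (need not be unit length).
#' @param angle rotation angle in radians.
#' @return 3x3 proper rotation matrix.
#' @examples
#' rotation_about_axis(c(0, 0, 1), pi / 2)
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- unitv(axis)
  c0 <- cos(angle); s0 <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c0 + s0 * K + (1 - c0) * (u %o% u)
}

## rotation matrix from a rotation vector (axis * angle); identity at w = 0
rotation_from_rotvec <- function(w) {
  th <- vnorm(w)
  if (th < 1e-12) return(diag(3))
  rotation_about_axis(w, th)
}

is_rotation_matrix <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

## ---- unit quaternions (w, x, y, z) ----

quat_identity <- function() c(1, 0, 0, 0)

quat_normalize <- function(q) q / sqrt(sum(q * q))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_rotvec <- function(w) {
  th <- vnorm(w)
  if (th < 1e-12) return(quat_identity())
  u <- w / th
  c(cos(th / 2), sin(th / 2) * u)
}

rotation_from_quat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

## angle (radians) of a proper rotation matrix
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

## ---- internal-coordinate atom placement (NeRF) ----

#' Place an atom from internal coordinates
#'
#' Given three reference positions a-b-c, places atom d with |c-d| = `bond`,
#' angle b-c-d = `angle` and dihedral a-b-c-d = `dihedral`.
#'
#' @param a,b,c 3-vectors, the reference frame atoms.
#' @param bond bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral torsion a-b-c-d in degrees.
#' @return 3-vector position of the new atom.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih), bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## measured torsion a-b-c-d in degrees
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## ---- least-squares superposition ----

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping `y` onto `x` with minimum
#' root-mean-square deviation.
#'
#' @param x reference coordinates, n x 3 matrix.
#' @param y mobile coordinates, n x 3 matrix (same n, corresponding rows).
#' @return list with `rotation` (3x3, det +1), `translation` (3-vector) such
#'   that `y %*% t(rotation) + translation` superposes onto `x`, the
#'   superposed coordinates `yfit`, and `rmsd` in Angstrom.
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' R <- rotation_about_axis(c(0, 0, 1), 0.7)
#' fit <- kabsch_superpose(x, x %*% t(R) + 5)
#' stopifnot(fit$rmsd < 1e-10)
#' @export
kabsch_superpose <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("coordinate sets must have equal dimensions")
  if (nrow(x) < 3) stop("need at least 3 points for superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  sv_y <- svd(yc)$d
  if (sv_y[2] < 1e-8 * max(sv_y[1], 1)) {
    stop("degenerate (collinear) coordinate set: superposition is not unique")
  }
  H <- crossprod(yc, xc)               # 3x3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cx - as.vector(R %*% cy)
  yfit <- y %*% t(R) + matrix(tr, nrow(y), 3, byrow = TRUE)
  list(rotation = R, translation = tr, yfit = yfit,
       rmsd = sqrt(mean(rowSums((yfit - x)^2))))
}

## deterministic seeding that leaves the caller's RNG stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
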