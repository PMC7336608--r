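# Small 3D geometry kernel: angles, dihedrals, superposition, internal-to-
# Cartesian chain building. All angles in degrees.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

#' Planar angle at b formed by points a-b-c
#'
#' Uses the arccos of the clamped normalised dot product, so exactly
#' collinear triples return 180 (or 0) instead of NaN.
#'
#' @param a,b,c numeric 3-vectors (coordinates, Angstrom).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
point_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  d <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(min(1, max(-1, d))) * 180 / pi
}

#' Dihedral angle defined by points a-b-c-d
#'
#' @param a,b,c,d numeric 3-vectors.
#' @return Signed torsion in degrees, in `(-180, 180]`.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(b2 / vnorm(b2), n1)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## Place atom D given A, B, C with bond |C-D|, angle B-C-D (deg) and torsion
## A-B-C-D (deg). Standard natural-extension-reference-frame construction.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * cos(tor) * sin(pi - ang),
          bond * sin(tor) * sin(pi - ang))
  bc <- c - b
  bc <- bc / vnorm(bc)
  n <- vcross(b - a, bc)
  n <- n / vnorm(n)
  m <- cbind(bc, vcross(n, bc), n)
  as.vector(m %*% d2) + c
}

#' Optimal least-squares superposition (Kabsch)
#'
#' Rotates and translates `mobile` onto `fixed` minimising the RMSD over
#' paired rows. Proper rotation enforced (determinant +1).
#'
#' @param mobile,fixed n x 3 coordinate matrices with paired rows.
#' @return n x 3 matrix: `mobile` superposed onto `fixed`.
#' @export
kabsch_superpose <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3, ncol(fixed) == 3)
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(fixed, 2, cf)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(P %*% t(R), 2, cf, "+")
}

## Random proper rotation matrix (for tests and invariance checks).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

## Express coordinates in the principal-axes frame of `ref` (defaults to X
## itself): centred on the mean of ref, axes = eigenvectors of the covariance
## of ref, each sign-fixed by its largest-magnitude component. The result is
## unchanged under proper rigid-body transforms of the input, which makes
## grid-sampled quantities computed in this frame rotation invariant.
canonical_frame <- function(X, ref = X) {
  ctr <- colMeans(ref)
  Rc <- sweep(ref, 2, ctr)
  ev <- eigen(crossprod(Rc) / nrow(Rc), symmetric = TRUE)$vectors
  for (k in 1:3) {
    j <- which.max(abs(ev[, k]))
    if (ev[j, k] < 0) ev[, k] <- -ev[, k]
  }
  sweep(X, 2, ctr) %*% ev
}

## Squared-distance matrix between rows of A and rows of B.
cross_dist <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
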