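#' @include AllClasses.R
NULL

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a^2))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a near-zero vector")
  a / n
}

#' Measure a signed dihedral angle
#'
#' Standard IUPAC right-handed convention; the returned value lies in
#' (-180, 180] and is invariant under rigid-body motion of the whole model.
#'
#' @param model a \linkS4class{MolecularModel}, or a 4 x 3 coordinate matrix.
#' @param quartet four distinct atom indices (i, j, k, l); ignored when
#'   \code{model} is already a 4 x 3 matrix.
#' @return Angle in degrees.
#' @examples
#' m <- makeToyGlycan()
#' measureDihedral(m, c(1, 2, 3, 4))
#' @export
measureDihedral <- function(model, quartet = NULL) {
  if (is(model, "MolecularModel")) {
    stopifnot(length(quartet) == 4L, !anyDuplicated(quartet))
    p <- coords(model)[quartet, , drop = FALSE]
  } else {
    p <- as.matrix(model)
    stopifnot(nrow(p) == 4L, ncol(p) == 3L)
  }
  if (!all(is.finite(p))) stop("non-finite coordinates in dihedral quartet")
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined dihedral: collinear atom triple")
  ang <- atan2(sum(vcross(n1, n2) * vunit(b2)), sum(n1 * n2)) * 180 / pi
  wrapAngle(ang)
}

# Rotation matrix for angle theta (radians) about unit axis u (Rodrigues).
rotationMatrix <- function(u, theta) {
  u <- vunit(u)
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * (u %o% u)
}

# Rotate rows of xyz about the axis through point o with direction u.
rotateAboutAxis <- function(xyz, o, u, thetaDeg) {
  R <- rotationMatrix(u, thetaDeg * pi / 180)
  sweep(sweep(xyz, 2, o) %*% t(R), 2, o, "+")
}

#' Set a dihedral angle by rigid rotation about the central bond
#'
#' Rotates \code{movingSet} about the j-k axis so that the dihedral over
#' \code{quartet} equals \code{target}. All distances internal to the moving
#' set, and all atoms outside it, are untouched.
#'
#' @param model a \linkS4class{MolecularModel}.
#' @param quartet atom indices (i, j, k, l).
#' @param target desired angle, degrees.
#' @param movingSet atom indices rotated with the l side of the bond. Must
#'   contain l and exclude i, j and k (atoms on the axis are permitted: they
#'   do not move).
#' @return The model with updated coordinates.
#' @export
setDihedral <- function(model, quartet, target, movingSet) {
  cur <- measureDihedral(model, quartet)
  delta <- wrapAngle(target - cur)
  xyz <- coords(model)
  j <- quartet[2]; k <- quartet[3]
  axis <- xyz[k, ] - xyz[j, ]
  # The rotation sense depends on which side of the bond movingSet lies;
  # try the right-hand sense about j->k first and mirror it if needed.
  for (sgn in c(1, -1)) {
    new <- xyz
    new[movingSet, ] <- rotateAboutAxis(xyz[movingSet, , drop = FALSE],
                                        xyz[k, ], axis, sgn * delta)
    coords(model) <- new
    got <- measureDihedral(model, quartet)
    if (abs(wrapAngle(got - target)) <= 1e-6) return(model)
  }
  stop(sprintf("setDihedral failed to reach target (%.6f vs %.6f)",
               got, target))
}

# Place point D from reference atoms A, B, C with bond length |C-D|, angle
# B-C-D (deg) and dihedral A-B-C-D (deg). Natural extension reference frame.
nerfPlace <- function(A, B, C, length, angleDeg, torsionDeg) {
  th <- angleDeg * pi / 180
  ph <- torsionDeg * pi / 180
  d2 <- c(-length * cos(th),
          length * sin(th) * cos(ph),
          length * sin(th) * sin(ph))
  bc <- vunit(C - B)
  n <- vunit(vcross(B - A, bc))
  m <- vcross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(C + M %*% d2)
}

# Least-squares rigid superposition (Kabsch): returns function mapping
# points expressed in the 'from' frame onto the 'to' frame.
kabschTransform <- function(from, to) {
  cf <- colMeans(from); ct <- colMeans(to)
  H <- t(sweep(from, 2, cf)) %*% sweep(to, 2, ct)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  function(x) sweep(sweep(x, 2, cf) %*% t(R), 2, ct, "+")
}
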