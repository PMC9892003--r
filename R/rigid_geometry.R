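#' Elementary rotation matrices (degrees, counterclockwise positive)
#'
#' Active rotations about the z and y axes; the angle is counterclockwise
#' when viewed from the positive end of the axis.
#'
#' @param theta Angle in degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(theta) {
  t <- theta * pi / 180
  c <- cos(t); s <- sin(t)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_y <- function(theta) {
  t <- theta * pi / 180
  c <- cos(t); s <- sin(t)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' Euler angles to rotation operator
#'
#' Builds the operator `M(rot, tilt, psi) = Rz(psi) %*% Ry(tilt) %*% Rz(rot)`
#' (intrinsic ZYZ) that maps tomogram-frame vectors into the particle
#' reference frame. The rows of `M` are the particle-frame basis vectors
#' expressed in tomogram coordinates; for a membrane-bound ribosome the
#' particle xy plane corresponds to the membrane plane.
#'
#' @param euler Numeric length-3 vector `(rot, tilt, psi)` in degrees.
#' @return 3x3 orthonormal matrix with determinant +1.
#' @export
euler_to_rotation <- function(euler) {
  euler <- as.numeric(euler)
  if (length(euler) != 3 || !all(is.finite(euler)))
    stop("euler must be three finite angles (rot, tilt, psi)")
  rot_z(euler[3]) %*% rot_y(euler[2]) %*% rot_z(euler[1])
}

#' Rotation operator to ZYZ Euler angles
#'
#' Inverse of [euler_to_rotation()]: recovers a canonical `(rot, tilt, psi)`
#' triple (rot, psi in \[-180, 180), tilt in \[0, 180\]) from an orthonormal
#' matrix. At the gimbal-lock poles (tilt = 0 or 180) psi is set to 0 and the
#' in-plane angle is carried by rot.
#'
#' @param M 3x3 rotation matrix as produced by [euler_to_rotation()].
#' @return Numeric vector `c(rot, tilt, psi)` in degrees.
#' @export
rotation_to_euler <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == c(3, 3)))
  ct <- max(-1, min(1, M[3, 3]))
  tilt <- acos(ct) * 180 / pi
  if (abs(ct) > 1 - 1e-12) {
    # M ~ Rz(psi +/- rot); fold everything into rot
    if (ct > 0) {
      rot <- atan2(M[2, 1], M[1, 1]) * 180 / pi
    } else {
      rot <- atan2(M[2, 1], -M[1, 1]) * 180 / pi
    }
    psi <- 0
  } else {
    rot <- atan2(M[3, 2], -M[3, 1]) * 180 / pi
    psi <- atan2(M[2, 3], M[1, 3]) * 180 / pi
  }
  eu <- canonicalize_euler(rot, tilt, psi)
  c(rot = eu$rot, tilt = eu$tilt, psi = eu$psi)
}

#' Express another particle's position in a focal particle's frame
#'
#' Computes `M(focal euler) %*% (other_position - focal_position)`: the
#' neighbour vector rotated with the inverse orientation of the focal
#' ribosome, i.e. the neighbour's coordinates in the focal particle's
#' reference frame. The Euclidean norm equals the inter-particle distance.
#'
#' @param focal A single-row data.frame or list with `x`, `y`, `z`, `rot`,
#'   `tilt`, `psi`.
#' @param other_position Numeric length-3 position (Angstrom, tomogram frame),
#'   or a matrix with one position per row.
#' @return Length-3 vector (or matrix with one row per input position) in the
#'   focal particle frame, Angstrom.
#' @export
to_particle_frame <- function(focal, other_position) {
  M <- euler_to_rotation(c(focal$rot, focal$tilt, focal$psi))
  p <- c(focal$x, focal$y, focal$z)
  if (is.matrix(other_position)) {
    d <- sweep(other_position, 2, p)
    t(M %*% t(d))
  } else {
    as.numeric(M %*% (as.numeric(other_position) - p))
  }
}

is_rotation_matrix <- function(M, tol = 1e-10) {
  is.matrix(M) && all(dim(M) == c(3, 3)) &&
    max(abs(crossprod(M) - diag(3))) <= tol &&
    abs(det(M) - 1) <= tol
}
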