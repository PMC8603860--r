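#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, acting on column
#' vectors. Angles are in degrees throughout the package.
#'
#' @param deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
#' @examples
#' rot_x(90) %*% c(0, 1, 0)  # maps +y to +z
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Check that a matrix is a proper rotation
#'
#' An orientation matrix must be orthonormal with determinant +1.
#'
#' @param R matrix to test.
#' @param tol numeric tolerance on orthonormality and the determinant.
#' @return `TRUE` or `FALSE` (`is_rotation`); `check_rotation` returns the
#'   matrix invisibly or throws an error.
#' @export
is_rotation <- function(R, tol = 1e-8) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

#' @rdname is_rotation
#' @export
check_rotation <- function(R, tol = 1e-8) {
  if (!is_rotation(R, tol)) {
    stop("not a valid orientation matrix (orthonormal, det +1) at tolerance ",
         format(tol), call. = FALSE)
  }
  invisible(R)
}

#' Compose a rotation from Euler angles, xyz sequence
#'
#' Builds `R = Rx(alpha) %*% Ry(beta) %*% Rz(gamma)`: an intrinsic x-y-z
#' rotation sequence (equivalently extrinsic z-y-x) acting on column
#' vectors. This is the single place the package's Euler convention lives;
#' [euler_xyz()] inverts it.
#'
#' @param alpha_x,beta_y,gamma_z angles in degrees.
#' @return A 3x3 rotation matrix.
#' @seealso [euler_xyz()]
#' @export
euler_to_matrix <- function(alpha_x, beta_y, gamma_z) {
  rot_x(alpha_x) %*% rot_y(beta_y) %*% rot_z(gamma_z)
}

# Vectorised elements of Rx(a)Ry(b)Rz(g); angles in degrees, n-vectors.
# Returns the nine element columns of each rotation matrix:
#   | cb*cg            -cb*sg            sb     |
#   | ca*sg + sa*sb*cg  ca*cg - sa*sb*sg -sa*cb |
#   | sa*sg - ca*sb*cg  sa*cg + ca*sb*sg  ca*cb |
euler_elements <- function(alpha_x, beta_y, gamma_z) {
  a <- alpha_x * pi / 180
  b <- beta_y * pi / 180
  g <- gamma_z * pi / 180
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  list(
    r11 = cb * cg, r12 = -cb * sg, r13 = sb,
    r21 = ca * sg + sa * sb * cg, r22 = ca * cg - sa * sb * sg, r23 = -sa * cb,
    r31 = sa * sg - ca * sb * cg, r32 = sa * cg + ca * sb * sg, r33 = ca * cb
  )
}

# Decompose rotation-matrix elements into xyz Euler angles (degrees),
# vectorised. beta is confined to [-90, 90]. Near gimbal lock
# (|cos beta| < gimbal_tol) gamma is set to 0 and alpha absorbs the
# remaining rotation about the locked axis.
euler_from_elements <- function(e, gimbal_tol = 1e-7, warn = TRUE) {
  sb <- pmin(pmax(e$r13, -1), 1)
  beta <- asin(sb)
  cb <- cos(beta)
  locked <- cb < gimbal_tol
  alpha <- atan2(-e$r23, e$r33)
  gamma <- atan2(-e$r12, e$r11)
  if (any(locked)) {
    if (warn) {
      warning("gimbal lock (|beta| ~ 90 deg) in ", sum(locked),
              " frame(s); gamma set to 0", call. = FALSE)
    }
    alpha[locked] <- atan2(e$r32[locked], e$r22[locked])
    gamma[locked] <- 0
  }
  cbind(x = alpha, y = beta, z = gamma) * 180 / pi
}

#' Euler angles of an orientation matrix, xyz sequence
#'
#' Inverts [euler_to_matrix()]: returns angles `(x, y, z)` in degrees with
#' `R = Rx(x) %*% Ry(y) %*% Rz(z)`. The middle angle is confined to
#' `[-90, 90]` degrees. At gimbal lock (`|y| = 90` degrees, where only the
#' sum/difference of the outer angles is determined) the z angle is set to 0,
#' the x angle absorbs the remaining rotation, and a warning is emitted.
#'
#' @param R a 3x3 orientation matrix.
#' @param tol tolerance for validating `R`.
#' @return Named numeric vector `c(x =, y =, z =)` in degrees.
#' @export
#' @examples
#' euler_xyz(euler_to_matrix(10, 20, 30))
euler_xyz <- function(R, tol = 1e-8) {
  check_rotation(R, tol)
  e <- list(r11 = R[1, 1], r12 = R[1, 2], r13 = R[1, 3],
            r21 = R[2, 1], r22 = R[2, 2], r23 = R[2, 3],
            r31 = R[3, 1], r32 = R[3, 2], r33 = R[3, 3])
  drop(euler_from_elements(e)[1, ])
}

#' Orientation relative to a reference
#'
#' Expresses orientation `R_t` relative to a reference orientation
#' `R_ref` (both given in the same world frame) as `t(R_ref) %*% R_t`.
#' Used to re-express head orientation relative to the neutral
#' central-fixation pose, which makes angle time series comparable across
#' devices with different world frames.
#'
#' @param R_t,R_ref orientation matrices.
#' @return A 3x3 orientation matrix; identity when `R_t == R_ref`.
#' @export
relative_orientation <- function(R_t, R_ref) {
  check_rotation(R_t)
  check_rotation(R_ref)
  crossprod(R_ref, R_t)
}

#' Chordal mean of orientation matrices
#'
#' The rotation matrix nearest (in Frobenius norm) to the elementwise
#' average of the inputs, obtained by orthogonal projection (SVD) of the
#' average onto the rotation group. For identical inputs it returns that
#' input; for a tight cluster of orientations it is the usual notion of an
#' average pose.
#'
#' @param Rs a list of 3x3 orientation matrices, or a 3-column matrix of
#'   stacked basis vectors as produced internally.
#' @return A 3x3 rotation matrix.
#' @export
mean_orientation <- function(Rs) {
  if (is.matrix(Rs)) Rs <- list(Rs)
  if (length(Rs) == 0L) stop("empty sequence of orientations", call. = FALSE)
  M <- Reduce(`+`, Rs) / length(Rs)
  project_rotation(M)
}

# Nearest rotation matrix to M in Frobenius norm (special orthogonal
# Procrustes projection).
project_rotation <- function(M) {
  s <- svd(M)
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, sign(d))) %*% t(s$v)
}
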