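# Rotation helpers shared by the attitude, inverse-dynamics and synthetic
# modules. Orientations follow the 3-2-1 (yaw-pitch-roll) Euler sequence:
# sensor-to-stationary matrix T = Rz(psi) %*% Ry(theta) %*% Rx(phi).

#' Rotation matrix from 3-2-1 Euler angles
#'
#' Builds the sensor-to-stationary rotation matrix for the yaw-pitch-roll
#' sequence: a vector expressed in the sensor frame is mapped to the
#' stationary frame by `T %*% v`.
#'
#' @param psi Yaw angle about the vertical z axis \[rad\].
#' @param theta Pitch angle about the intermediate y axis \[rad\].
#' @param phi Roll angle about the sensor x axis \[rad\].
#'
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' euler_to_matrix(0, 0, 0)            # identity
#' euler_to_matrix(pi / 2, 0, 0) %*% c(1, 0, 0)  # -> (0, 1, 0)
#' @export
euler_to_matrix <- function(psi, theta, phi) {
  cps <- cos(psi); sps <- sin(psi)
  cth <- cos(theta); sth <- sin(theta)
  cph <- cos(phi); sph <- sin(phi)
  matrix(c(
    cth * cps, sph * sth * cps - cph * sps, cph * sth * cps + sph * sps,
    cth * sps, cph * cps + sph * sth * sps, -sph * cps + cph * sth * sps,
    -sth,      sph * cth,                   cph * cth
  ), nrow = 3, byrow = TRUE)
}

# Vectorised version: returns a 3 x 3 x n array for angle vectors.
euler_to_matrices <- function(psi, theta, phi) {
  n <- length(theta)
  if (length(psi) == 1L) psi <- rep(psi, n)
  if (length(phi) == 1L) phi <- rep(phi, n)
  stopifnot(length(psi) == n, length(phi) == n)
  arr <- array(0, dim = c(3, 3, n))
  cps <- cos(psi); sps <- sin(psi)
  cth <- cos(theta); sth <- sin(theta)
  cph <- cos(phi); sph <- sin(phi)
  arr[1, 1, ] <- cth * cps
  arr[1, 2, ] <- sph * sth * cps - cph * sps
  arr[1, 3, ] <- cph * sth * cps + sph * sps
  arr[2, 1, ] <- cth * sps
  arr[2, 2, ] <- cph * cps + sph * sth * sps
  arr[2, 3, ] <- -sph * cps + cph * sth * sps
  arr[3, 1, ] <- -sth
  arr[3, 2, ] <- sph * cth
  arr[3, 3, ] <- cph * cth
  arr
}

# Apply a 3x3xn rotation array to the rows of an n x 3 matrix:
# out[k, ] = R[, , k] %*% v[k, ]  (transpose = TRUE applies R^T).
rotate_rows <- function(R, v, transpose = FALSE) {
  n <- dim(R)[3]
  stopifnot(nrow(v) == n)
  r11 <- R[1, 1, ]; r12 <- R[1, 2, ]; r13 <- R[1, 3, ]
  r21 <- R[2, 1, ]; r22 <- R[2, 2, ]; r23 <- R[2, 3, ]
  r31 <- R[3, 1, ]; r32 <- R[3, 2, ]; r33 <- R[3, 3, ]
  x <- v[, 1]; y <- v[, 2]; z <- v[, 3]
  if (transpose) {
    cbind(r11 * x + r21 * y + r31 * z,
          r12 * x + r22 * y + r32 * z,
          r13 * x + r23 * y + r33 * z, deparse.level = 0)
  } else {
    cbind(r11 * x + r12 * y + r13 * z,
          r21 * x + r22 * y + r23 * z,
          r31 * x + r32 * y + r33 * z, deparse.level = 0)
  }
}

# Row-wise cross product of two n x 3 matrices (or one 3-vector recycled).
cross_rows <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow(b), 3, byrow = TRUE)
  if (is.null(dim(b))) b <- matrix(b, nrow(a), 3, byrow = TRUE)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1], deparse.level = 0)
}
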