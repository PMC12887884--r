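#' Rigid-body pose
#'
#' A pose is a proper rigid transform: world coordinates are
#' `x %*% t(R) + t` for body-frame coordinates `x` (rows). The glycan is
#' stored in a body frame centred on its charge centroid, so `t` is the
#' world position of that centroid.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation (Angstrom).
#' @return an object of class `rigid_pose`.
#' @export
rigid_pose <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3L, 3L)), length(t) == 3L,
            all(is.finite(R)), all(is.finite(t)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R is not a proper rotation matrix")
  structure(list(R = R, t = t), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("<rigid_pose> t = (", paste(signif(x$t, 5), collapse = ", "), ")\n")
  invisible(x)
}

#' Apply a rigid pose to body-frame coordinates
#'
#' @param pose a [rigid_pose()].
#' @param x n x 3 matrix (or length-3 vector) of body-frame coordinates.
#' @return n x 3 matrix of world coordinates.
#' @export
pose_apply <- function(pose, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  sweep(x %*% t(pose$R), 2, pose$t, "+")
}

#' Rotation matrix about an axis
#'
#' Rodrigues formula; `axis` need not be normalized.
#'
#' @param axis length-3 axis vector.
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) return(diag(3))
  u <- axis / n
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Uniformly random orientation
#'
#' Draws a rotation matrix uniformly over SO(3) via a normalized Gaussian
#' quaternion. Consumes 4 values from the R random stream.
#'
#' @return 3x3 rotation matrix.
#' @export
random_orientation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

## Re-orthonormalize a drifting rotation matrix (Gram-Schmidt on columns).
.orthonormalize <- function(R) {
  a <- R[, 1] / sqrt(sum(R[, 1]^2))
  b <- R[, 2] - sum(a * R[, 2]) * a
  b <- b / sqrt(sum(b^2))
  cbind(a, b, c(a[2] * b[3] - a[3] * b[2],
                a[3] * b[1] - a[1] * b[3],
                a[1] * b[2] - a[2] * b[1]), deparse.level = 0)
}
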