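#' Rigid 3D rotation from two tilt angles
#'
#' Builds the rotation `Rx(alpha_x) %*% Ry(alpha_y)` about a pivot point.
#' Two angles parameterise an axis direction minimally; torsion about z is
#' irrelevant to the optical-axis direction and is not modelled.
#'
#' @param alpha_x,alpha_y tilt angles in degrees, each in (-90, 90).
#' @param pivot rotation pivot `(x, y, z)` in mm; default the anterior apex.
#' @return an object of class `rigid_rotation` with fields `matrix`
#'   (3x3 orthonormal, det +1), `pivot`, `alpha_x`, `alpha_y`.
#' @examples
#' r <- rotation_from_angles(3, 4)
#' apply_rotation(r, c(0, 0, 1))
#' @export
rotation_from_angles <- function(alpha_x, alpha_y, pivot = c(0, 0, 0)) {
  stopifnot(length(alpha_x) == 1, length(alpha_y) == 1, length(pivot) == 3,
            is.finite(alpha_x), is.finite(alpha_y), all(is.finite(pivot)))
  if (abs(alpha_x) >= 90 || abs(alpha_y) >= 90)
    stop("tilt angles must lie in (-90, 90) degrees")
  ax <- deg2rad(alpha_x); ay <- deg2rad(alpha_y)
  rx <- matrix(c(1, 0, 0,
                 0, cos(ax), -sin(ax),
                 0, sin(ax), cos(ax)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay),
                 0, 1, 0,
                 -sin(ay), 0, cos(ay)), 3, 3, byrow = TRUE)
  structure(
    list(matrix = rx %*% ry, pivot = as.numeric(pivot),
         alpha_x = alpha_x, alpha_y = alpha_y),
    class = "rigid_rotation"
  )
}

#' Apply a rigid rotation to points
#'
#' @param rotation a [rotation_from_angles()] result.
#' @param points a 3-vector or an n x 3 matrix of points in mm.
#' @return rotated points, same shape as the input.
#' @export
apply_rotation <- function(rotation, points) {
  stopifnot(inherits(rotation, "rigid_rotation"))
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else as.matrix(points)
  out <- sweep(p, 2, rotation$pivot) %*% t(rotation$matrix)
  out <- sweep(out, 2, rotation$pivot, `+`)
  if (single) as.numeric(out) else out
}

# inverse mapping: instrument frame -> unrotated model frame
apply_rotation_inverse <- function(rotation, points) {
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 3) else as.matrix(points)
  out <- sweep(p, 2, rotation$pivot) %*% rotation$matrix
  out <- sweep(out, 2, rotation$pivot, `+`)
  if (single) as.numeric(out) else out
}

#' @export
print.rigid_rotation <- function(x, ...) {
  cat(sprintf("<rigid_rotation> alpha_x=%.4g deg, alpha_y=%.4g deg, pivot=(%g, %g, %g)\n",
              x$alpha_x, x$alpha_y, x$pivot[1], x$pivot[2], x$pivot[3]))
  invisible(x)
}

#' Angle between two axis directions
#'
#' Arc-cosine of the dot product of two unit vectors, with the dot product
#' clamped to `[-1, 1]` so rounding can never produce `NaN`.
#'
#' @param u,v unit 3-vectors.
#' @return angle in degrees, in `[0, 180]`.
#' @export
angle_between_axes <- function(u, v) {
  stopifnot(length(u) == 3, length(v) == 3)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("zero-length axis vector")
  rad2deg(acos(max(-1, min(1, sum(u * v) / (nu * nv)))))
}
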