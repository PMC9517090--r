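#' Rigid transform in 3D
#'
#' A proper rigid-body transform \eqn{x \mapsto R x + t} with \eqn{R} a 3x3
#' rotation matrix (orthonormal, determinant +1) and \eqn{t} a translation in
#' millimetres. All alignment results in the package are carried as objects of
#' this class; the transform maps postoperative (T1) coordinates into planned
#' (T0) space when produced by registration.
#'
#' The constructor checks orthonormality and handedness and then snaps the
#' rotation to the nearest orthonormal matrix (polar projection via SVD) so
#' that long chains of compositions do not drift.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' rigid_transform()                       # identity
#' rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(1, 0, 0))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    stop("`rotation` must be a finite 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("`translation` must be a finite length-3 numeric", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("`rotation` is not orthonormal (R'R != I within 1e-6)", call. = FALSE)
  }
  if (det(rotation) < 0) {
    stop("`rotation` is a reflection (det < 0), not a proper rotation",
         call. = FALSE)
  }
  s <- svd(rotation)
  rotation <- s$u %*% t(s$v)   # polar projection keeps R'R = I to ~1e-15
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>  rotation", sprintf("%.4f deg", rotation_angle(x)),
      " translation [", paste(sprintf("%.4f", x$translation), collapse = ", "),
      "] mm\n")
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 numeric matrix of coordinates (mm).
#' @return n x 3 matrix of transformed coordinates.
#' @export
transform_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  points <- as_point_matrix(points)
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `second` after `first`,
#' i.e. `compose_transforms(second, first)(x) = second(first(x))`.
#'
#' @param second,first [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(second, first) {
  stopifnot(inherits(second, "rigid_transform"),
            inherits(first, "rigid_transform"))
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Rotation angle of a rigid transform
#'
#' The geodesic rotation angle, in degrees, of the rotation part; 0 for a pure
#' translation. Used to report registration-recovery errors.
#'
#' @param transform A [rigid_transform()] or a 3x3 rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(transform) {
  R <- if (inherits(transform, "rigid_transform")) transform$rotation
       else transform
  ct <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Rotation matrix about an axis
#'
#' Rodrigues' formula for the rotation of `angle_deg` degrees about `axis`
#' (right-hand rule; the axis is normalised internally).
#'
#' @param axis numeric length-3 axis direction.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero", call. = FALSE)
  a <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# uniform random rotation with angle <= max_angle_deg (axis uniform on the
# sphere, angle uniform on [0, max]); draws from the caller's RNG stream
random_rotation <- function(max_angle_deg) {
  ax <- stats::rnorm(3)
  rotation_about_axis(ax, stats::runif(1, 0, max_angle_deg))
}

# coerce to an n x 3 double matrix
as_point_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must have 3 columns", call. = FALSE)
  storage.mode(points) <- "double"
  points
}
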