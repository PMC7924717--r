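#' Rigid 6-DOF poses
#'
#' A pose is the rigid transform that a tracked marker (or any other 6-DOF
#' input) imposes on the molecule anchored to it: a proper rotation, a
#' translation in Angstrom, and a display-only zoom factor. Physics and
#' observables always operate at `scale = 1`; the zoom is honoured only when
#' exporting meshes for display (see [write_obj_ballstick()]).
#'
#' @param rotation either a unit quaternion `c(w, x, y, z)` or a 3x3
#'   orthonormal rotation matrix with determinant +1.
#' @param translation numeric 3-vector, Angstrom.
#' @param scale positive zoom factor (display only), default 1.
#' @return an object of class `mol_pose` with elements `q` (unit quaternion,
#'   w-first), `R` (3x3 rotation matrix), `translation`, `scale`.
#' @examples
#' p <- pose(rotation = c(1, 0, 0, 0), translation = c(10, 0, 0))
#' apply_pose(rbind(c(0, 0, 0), c(1.5, 0, 0)), p)
#' @export
pose <- function(rotation = c(1, 0, 0, 0), translation = c(0, 0, 0), scale = 1) {
  if (is.matrix(rotation)) {
    R <- check_rotation_matrix(rotation)
    q <- mat_to_quat(R)
  } else {
    q <- check_quaternion(rotation)
    R <- quat_to_mat(q)
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite 3-vector")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a positive number")
  structure(list(q = q, R = R, translation = translation, scale = scale),
            class = "mol_pose")
}

#' @export
print.mol_pose <- function(x, ...) {
  cat("mol_pose: q = [", paste(signif(x$q, 6), collapse = ", "),
      "], t = [", paste(signif(x$translation, 6), collapse = ", "),
      "], scale =", x$scale, "\n")
  invisible(x)
}

check_quaternion <- function(q, tol = 1e-9) {
  q <- as.numeric(q)
  if (length(q) != 4L || !all(is.finite(q)))
    stop("quaternion must be a finite 4-vector (w, x, y, z)")
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > tol)
    stop(sprintf("quaternion is not unit length (|q| = %.12g)", n))
  q / n
}

check_rotation_matrix <- function(R, tol = 1e-9) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3L, 3L))) stop("rotation matrix must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation matrix is not orthonormal")
  if (abs(det(R) - 1) > sqrt(tol))
    stop("rotation matrix must have determinant +1 (no reflections)")
  R
}

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

#' Random rotation quaternion
#'
#' Uniform over SO(3) (Shoemake's subgroup algorithm). Used by fixture
#' generators and property tests.
#'
#' @param n number of quaternions.
#' @return n x 4 matrix of unit quaternions (w, x, y, z).
#' @export
random_quaternion <- function(n = 1) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  q <- cbind(sqrt(u1) * cos(2 * pi * u3),
             sqrt(1 - u1) * sin(2 * pi * u2),
             sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3))
  q
}

as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  points
}

#' Apply a pose to a set of points
#'
#' Each output point is `R %*% (scale * (p - anchor)) + translation`: the
#' anchor point maps exactly onto the pose translation, mimicking a molecule
#' pinned to the centre of its marker through a chosen anchor atom. With
#' `scale = 1` the map is an isometry.
#'
#' @param points n x 3 matrix (or length-3 vector), Angstrom.
#' @param pose a [pose()].
#' @param anchor 3-vector subtracted before rotating (default origin).
#' @param apply_scale if `FALSE`, the pose's zoom factor is ignored (the
#'   default inside physics and observables).
#' @return n x 3 matrix of transformed points.
#' @export
apply_pose <- function(points, pose, anchor = c(0, 0, 0), apply_scale = TRUE) {
  stopifnot(inherits(pose, "mol_pose"))
  points <- as_points(points)
  anchor <- as.numeric(anchor)
  if (length(anchor) != 3L) stop("anchor must be a 3-vector")
  s <- if (apply_scale) pose$scale else 1
  centered <- sweep(points, 2, anchor) * s
  out <- centered %*% t(pose$R)
  sweep(out, 2, pose$translation, "+")
}

#' Interpolate between two poses
#'
#' Translation (and scale) are linearly interpolated; rotation follows the
#' shortest great-circle arc between the two quaternions (slerp). This is the
#' primitive behind predefined "binding coordinates" that carry a molecule
#' from its current pose into a target pose.
#'
#' @param current,target poses.
#' @param t interpolation fraction in \[0, 1\]; 0 returns `current`, 1
#'   returns `target`.
#' @return a [pose()].
#' @export
interpolate_pose <- function(current, target, t) {
  stopifnot(inherits(current, "mol_pose"), inherits(target, "mol_pose"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0 || t > 1)
    stop("t must be a number in [0, 1]")
  q1 <- current$q; q2 <- target$q
  d <- sum(q1 * q2)
  if (d < 0) { q2 <- -q2; d <- -d }        # shortest arc
  if (d > 1 - 1e-12) {
    q <- (1 - t) * q1 + t * q2             # nearly parallel: lerp
  } else {
    th <- acos(min(1, d))
    q <- (sin((1 - t) * th) * q1 + sin(t * th) * q2) / sin(th)
  }
  q <- q / sqrt(sum(q^2))
  pose(rotation = q,
       translation = (1 - t) * current$translation + t * target$translation,
       scale = (1 - t) * current$scale + t * target$scale)
}
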