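#' Planar pose
#'
#' A rigid 2D pose: position in meters and heading in radians,
#' counter-clockwise from the +x axis. Headings are always stored wrapped
#' to (-pi, pi]. This is the state propagated by dead reckoning and the
#' per-tag state optimised by the pose graph.
#'
#' @param x,y position, meters.
#' @param theta heading, radians (wrapped on construction).
#' @return An object of class \code{pose2d}: a named numeric vector
#'   \code{c(x, y, theta)}.
#' @examples
#' pose2d(1, 0, pi / 2)
#' @export
pose2d <- function(x = 0, y = 0, theta = 0) {
  stopifnot(is.numeric(x), is.numeric(y), is.numeric(theta),
            length(x) == 1, length(y) == 1, length(theta) == 1,
            is.finite(x), is.finite(y), is.finite(theta))
  structure(c(x = x, y = y, theta = wrap_angle(theta)), class = "pose2d")
}

#' @export
print.pose2d <- function(x, ...) {
  cat(sprintf("<pose2d> x = %.4f m, y = %.4f m, theta = %.4f rad\n",
              x[["x"]], x[["y"]], x[["theta"]]))
  invisible(x)
}

as_pose2d <- function(p) {
  if (inherits(p, "pose2d")) return(p)
  stopifnot(is.numeric(p), length(p) == 3)
  pose2d(p[[1]], p[[2]], p[[3]])
}

#' Wrap an angle to (-pi, pi]
#'
#' The boundary maps to +pi, so \code{wrap_angle(pi) == pi} and
#' \code{wrap_angle(-pi) == pi}. Vectorised.
#'
#' @param a angle(s), radians; must be finite.
#' @return angle(s) in (-pi, pi], equal to \code{a} modulo 2*pi.
#' @export
wrap_angle <- function(a) {
  if (!is.numeric(a) || any(!is.finite(a)))
    stop("wrap_angle(): angle must be finite", call. = FALSE)
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  # floor() puts the result in [-pi, pi); move the lower boundary to +pi
  w[w <= -pi] <- pi
  w
}

#' Compose two planar poses
#'
#' Rigid composition \code{a (+) b}: b's translation is rotated by a's
#' heading and added to a's translation; headings add (wrapped). Used for
#' chaining odometry increments and for tag/robot frame algebra.
#'
#' @param a,b \code{pose2d} objects (or length-3 numerics).
#' @return A \code{pose2d}.
#' @export
pose_compose <- function(a, b) {
  a <- as_pose2d(a); b <- as_pose2d(b)
  ca <- cos(a[["theta"]]); sa <- sin(a[["theta"]])
  pose2d(a[["x"]] + ca * b[["x"]] - sa * b[["y"]],
         a[["y"]] + sa * b[["x"]] + ca * b[["y"]],
         a[["theta"]] + b[["theta"]])
}

#' Invert a planar pose
#'
#' Two-sided inverse under \code{\link{pose_compose}}:
#' \code{pose_compose(p, pose_inverse(p))} is the identity pose.
#'
#' @param p a \code{pose2d}.
#' @return A \code{pose2d}.
#' @export
pose_inverse <- function(p) {
  p <- as_pose2d(p)
  ct <- cos(p[["theta"]]); st <- sin(p[["theta"]])
  pose2d(-( ct * p[["x"]] + st * p[["y"]]),
         -(-st * p[["x"]] + ct * p[["y"]]),
         -p[["theta"]])
}

#' Express pose b in the frame of pose a
#'
#' \code{pose_between(a, b)} returns the relative pose t such that
#' \code{pose_compose(a, t) == b}.
#'
#' @param a,b \code{pose2d} objects.
#' @return A \code{pose2d}.
#' @export
pose_between <- function(a, b) {
  pose_compose(pose_inverse(a), b)
}
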