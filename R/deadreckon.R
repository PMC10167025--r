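# Wheel-encoder / IMU dead reckoning.

#' One dead-reckoning step
#'
#' Propagates a planar pose by one sensor interval: the heading advances
#' by the IMU increment, the position by the mean wheel displacement
#' along the PRE-update heading:
#' \deqn{x' = x + (\Delta s_l + \Delta s_r) \cos\theta / 2}
#' so a pure spin (\code{dsl = -dsr}) leaves the position fixed.
#'
#' @param pose current \code{\link{pose2d}}.
#' @param dtheta IMU heading increment, radians.
#' @param dsl,dsr left/right wheel displacements, meters.
#' @return The propagated \code{pose2d}.
#' @export
dead_reckon_step <- function(pose, dtheta, dsl, dsr) {
  pose <- as_pose2d(pose)
  stopifnot(is.finite(dtheta), is.finite(dsl), is.finite(dsr))
  ds <- (dsl + dsr) / 2
  pose2d(pose[["x"]] + ds * cos(pose[["theta"]]),
         pose[["y"]] + ds * sin(pose[["theta"]]),
         pose[["theta"]] + dtheta)
}

#' Integrate a sensor log by dead reckoning
#'
#' Folds \code{\link{dead_reckon_step}} over the log's odometry samples.
#'
#' @param log a \code{\link{sensor_log}} (time-ordered).
#' @param start starting \code{\link{pose2d}} (default origin).
#' @return data.frame with columns \code{t}, \code{x}, \code{y},
#'   \code{theta}; one row per sample plus the starting pose (its
#'   timestamp is the first sample's, or 0 for an empty log).
#' @export
integrate_odometry <- function(log, start = pose2d()) {
  stopifnot(inherits(log, "sensor_log"))
  s <- log$samples
  n <- nrow(s)
  x <- y <- th <- numeric(n + 1)
  p <- as_pose2d(start)
  x[1] <- p[["x"]]; y[1] <- p[["y"]]; th[1] <- p[["theta"]]
  # unrolled fold (avoids per-step S3 dispatch on long logs)
  for (k in seq_len(n)) {
    ds <- (s$dsl[k] + s$dsr[k]) / 2
    x[k + 1] <- x[k] + ds * cos(th[k])
    y[k + 1] <- y[k] + ds * sin(th[k])
    th[k + 1] <- th[k] + s$dtheta[k]
  }
  data.frame(t = c(if (n) s$t[1] else 0, if (n) s$t else numeric()),
             x = x, y = y, theta = wrap_angle(th))
}
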