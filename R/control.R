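# Velocity control: anti-windup PI on heading, proportional on distance,
# differential-drive wheel mapping, and a closed-loop drive simulation.

#' Controller gains
#'
#' Heading is tracked by an anti-windup PI controller (integral clamped at
#' \code{integral_limit}); linear speed by a proportional controller
#' saturated at \code{v_max} so the platform decelerates into the goal
#' without overshoot. The control loop runs at \code{rate} Hz.
#'
#' @param kp_lin proportional gain on distance, 1/s.
#' @param kp_ang,ki_ang PI gains on heading error, 1/s and 1/s^2.
#' @param integral_limit anti-windup clamp on the heading-error integral,
#'   rad*s.
#' @param v_max linear speed limit, m/s.
#' @param omega_max angular speed limit, rad/s.
#' @param rate control frequency, Hz.
#' @param goal_tolerance distance below which the platform is considered
#'   at the target and both outputs are zeroed, meters.
#' @return An object of class \code{control_gains}.
#' @export
control_gains <- function(kp_lin = 0.5, kp_ang = 2.0, ki_ang = 0.2,
                          integral_limit = 0.5, v_max = 0.3,
                          omega_max = 1.0, rate = 50, goal_tolerance = 0.03) {
  vals <- c(kp_lin, kp_ang, ki_ang, integral_limit, v_max, omega_max,
            rate, goal_tolerance)
  if (any(!is.finite(vals)) || any(vals < 0) || rate <= 0)
    stop("control_gains(): gains must be non-negative and rate positive",
         call. = FALSE)
  structure(list(kp_lin = kp_lin, kp_ang = kp_ang, ki_ang = ki_ang,
                 integral_limit = integral_limit, v_max = v_max,
                 omega_max = omega_max, rate = rate,
                 goal_tolerance = goal_tolerance),
            class = "control_gains")
}

#' Controller state
#'
#' Distance and heading to the local target plus the PI integral
#' accumulator, carried between control steps.
#'
#' @param integral initial integral accumulator.
#' @return An object of class \code{controller_state}.
#' @export
controller_state <- function(integral = 0) {
  structure(list(dis_local = 0, yaw_local = 0, integral = integral),
            class = "controller_state")
}

clamp <- function(x, lim) pmin(pmax(x, -lim), lim)

#' One velocity-control step
#'
#' Computes the distance and (wrapped) bearing to the local target, then
#' \code{omega = kp_ang * yaw + ki_ang * integral} with the integral and
#' the output clamped, and \code{v = min(kp_lin * dis, v_max)}. Within
#' \code{goal_tolerance} of the target both commands are zero.
#'
#' @param pose current robot \code{\link{pose2d}}.
#' @param target target \code{\link{pose2d}} (only its position is used).
#' @param gains a \code{\link{control_gains}}.
#' @param state a \code{\link{controller_state}}.
#' @param dt time step, seconds (> 0).
#' @return list(v, omega, state) with the updated state (dis_local,
#'   yaw_local, integral).
#' @export
control_step <- function(pose, target, gains, state = controller_state(),
                         dt = 1 / gains$rate) {
  stopifnot(inherits(gains, "control_gains"), dt > 0)
  pose <- as_pose2d(pose); target <- as_pose2d(target)
  dx <- target[["x"]] - pose[["x"]]; dy <- target[["y"]] - pose[["y"]]
  dis <- sqrt(dx^2 + dy^2)
  if (dis < gains$goal_tolerance) {
    state$dis_local <- dis; state$yaw_local <- 0
    return(list(v = 0, omega = 0, state = state))
  }
  yaw <- wrap_angle(atan2(dy, dx) - pose[["theta"]])
  state$integral <- clamp(state$integral + yaw * dt, gains$integral_limit)
  omega <- clamp(gains$kp_ang * yaw + gains$ki_ang * state$integral,
                 gains$omega_max)
  v <- min(gains$kp_lin * dis, gains$v_max)
  state$dis_local <- dis; state$yaw_local <- yaw
  list(v = v, omega = omega, state = state)
}

#' Differential-drive wheel speeds
#'
#' Maps body velocities to wheel rim speeds:
#' \code{v_left = v - omega * b / 2}, \code{v_right = v + omega * b / 2};
#' with \code{v = 0} the platform spins on the spot.
#'
#' @param v linear velocity, m/s.
#' @param omega angular velocity, rad/s.
#' @param track_width wheel separation b, meters (> 0).
#' @return Named numeric \code{c(left, right)}.
#' @export
wheel_speeds <- function(v, omega, track_width) {
  if (track_width <= 0) stop("track_width must be positive", call. = FALSE)
  c(left = v - omega * track_width / 2, right = v + omega * track_width / 2)
}

#' Body velocities from wheel speeds
#' @param left,right wheel rim speeds, m/s.
#' @inheritParams wheel_speeds
#' @return Named numeric \code{c(v, omega)}.
#' @export
body_speeds <- function(left, right, track_width) {
  if (track_width <= 0) stop("track_width must be positive", call. = FALSE)
  c(v = (left + right) / 2, omega = (right - left) / track_width)
}

#' Closed-loop drive simulation along a planned path
#'
#' Simulates unicycle kinematics under the PI/P controller, following the
#' path with the tag-two-ahead local targeting rule: the local target
#' advances when the robot's along-path projection passes the next path
#' tag, and is never set beyond the final tag. Used to check goal
#' convergence, overshoot and heading-error bounds at a commanded speed.
#'
#' @param map a \code{\link{tag_map}}.
#' @param path integer vector of tag ids (>= 2) from
#'   \code{\link{plan_path}}.
#' @param gains a \code{\link{control_gains}}; set \code{v_max} to the
#'   commanded platform speed.
#' @param dt integration step, seconds (default one control period).
#' @param max_time simulation cap, seconds.
#' @return list with \code{trajectory} (data.frame t, x, y, theta, v,
#'   omega, dis_local, yaw_local, target_id), \code{reached} (logical),
#'   \code{overshoot} (meters past the goal along the final approach,
#'   >= 0) and \code{time} (seconds to reach the goal).
#' @export
drive_to_goal <- function(map, path, gains = control_gains(),
                          dt = 1 / gains$rate, max_time = 600) {
  stopifnot(inherits(map, "tag_map"), length(path) >= 2)
  wp <- t(vapply(path, function(id) {
    p <- tag_pose(map, id); c(p[["x"]], p[["y"]])
  }, numeric(2)))
  goal <- wp[nrow(wp), ]
  start <- tag_pose(map, path[1])
  pose <- pose2d(start[["x"]], start[["y"]],
                 atan2(wp[2, 2] - wp[1, 2], wp[2, 1] - wp[1, 1]))
  state <- controller_state()
  passed <- 1L  # start tag counts as passed
  n_max <- ceiling(max_time / dt)
  rec <- matrix(NA_real_, n_max, 9)
  reached <- FALSE; overshoot <- 0; k <- 0L
  # unit direction of the final approach, for overshoot measurement
  fin_dir <- goal - wp[nrow(wp) - 1, ]
  fin_dir <- fin_dir / sqrt(sum(fin_dir^2))
  while (k < n_max) {
    k <- k + 1L
    # advance "passed" while the projection onto the next segment is behind us
    while (passed < length(path)) {
      nxt <- wp[passed + 1L, ]
      seg <- nxt - wp[passed, ]
      ahead <- sum((c(pose[["x"]], pose[["y"]]) - nxt) * seg)
      if (ahead >= 0) passed <- passed + 1L else break
    }
    target_id <- local_target(path, passed)
    target <- tag_pose(map, target_id)
    cs <- control_step(pose, target, gains, state, dt)
    state <- cs$state
    rec[k, ] <- c((k - 1) * dt, pose[["x"]], pose[["y"]], pose[["theta"]],
                  cs$v, cs$omega, state$dis_local, state$yaw_local, target_id)
    beyond <- sum((c(pose[["x"]], pose[["y"]]) - goal) * fin_dir)
    overshoot <- max(overshoot, beyond)
    if (sqrt(sum((c(pose[["x"]], pose[["y"]]) - goal)^2)) < gains$goal_tolerance &&
        target_id == path[length(path)]) {
      reached <- TRUE
      break
    }
    # unicycle kinematics, pre-update heading (consistent with dead reckoning)
    pose <- pose2d(pose[["x"]] + cs$v * cos(pose[["theta"]]) * dt,
                   pose[["y"]] + cs$v * sin(pose[["theta"]]) * dt,
                   pose[["theta"]] + cs$omega * dt)
  }
  traj <- as.data.frame(rec[seq_len(k), , drop = FALSE])
  names(traj) <- c("t", "x", "y", "theta", "v", "omega",
                   "dis_local", "yaw_local", "target_id")
  list(trajectory = traj, reached = reached, overshoot = max(0, overshoot),
       time = (k - 1) * dt)
}
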