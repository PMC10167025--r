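# Synthetic plant-factory world: tag layouts, a differential-drive robot
# with noisy sensors, and a pinhole-projected fruit detection stream. The
# generator is the ground-truth oracle for every other module.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Sensor and detector noise model
#'
#' All noise sources of the simulator. Rates are probabilities in [0, 1];
#' standard deviations are per sample.
#'
#' @param encoder_sd_per_m encoder noise sd as a fraction of the distance
#'   travelled in the sample (1\% of distance by default).
#' @param imu_sd IMU heading-increment noise sd per sample, radians.
#' @param imu_bias constant IMU drift, rad/s.
#' @param obs_trans_sd,obs_rot_sd tag-observation noise sd, meters /
#'   radians (defaults 5 mm, 0.5 degree).
#' @param tag_range tag detection range, meters.
#' @param fn_rate detector false-negative rate per true fruit per frame.
#' @param fp_rate detector false-positive rate per frame.
#' @param flip_prob probability a detection's ripeness label is flipped.
#' @param bbox_jitter_sd bounding-box corner jitter sd, pixels.
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(encoder_sd_per_m = 0.01, imu_sd = 0.002,
                        imu_bias = 0, obs_trans_sd = 0.005,
                        obs_rot_sd = 0.5 * pi / 180, tag_range = 0.5,
                        fn_rate = 0.02, fp_rate = 0.02, flip_prob = 0,
                        bbox_jitter_sd = 0) {
  rates <- c(fn_rate, fp_rate, flip_prob)
  sds <- c(encoder_sd_per_m, imu_sd, obs_trans_sd, obs_rot_sd, bbox_jitter_sd)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]", call. = FALSE)
  if (any(sds < 0)) stop("noise sds must be >= 0", call. = FALSE)
  if (tag_range <= 0) stop("tag_range must be positive", call. = FALSE)
  structure(list(encoder_sd_per_m = encoder_sd_per_m, imu_sd = imu_sd,
                 imu_bias = imu_bias, obs_trans_sd = obs_trans_sd,
                 obs_rot_sd = obs_rot_sd, tag_range = tag_range,
                 fn_rate = fn_rate, fp_rate = fp_rate,
                 flip_prob = flip_prob, bbox_jitter_sd = bbox_jitter_sd),
            class = "noise_model")
}

#' Zero-noise model
#' @return A \code{\link{noise_model}} with every noise source off.
#' @export
noiseless <- function() {
  noise_model(encoder_sd_per_m = 0, imu_sd = 0, imu_bias = 0,
              obs_trans_sd = 0, obs_rot_sd = 0, fn_rate = 0, fp_rate = 0,
              flip_prob = 0, bbox_jitter_sd = 0)
}

#' Ground-truth tag layout
#'
#' Tags on straight segments with consecutive adjacency, emulating ground
#' fiducials pasted along the growing rows (default spacing 1.3 m).
#' \code{"line"} is a single straight corridor; \code{"loop"} walks a
#' rectangle (two aisles joined by turns) and closes the route back to
#' tag 0, the charging-pile tag.
#'
#' @param count number of tags (>= 2).
#' @param spacing tag spacing along the route, meters (> 0).
#' @param geometry \code{"line"} or \code{"loop"}.
#' @param aisle_width rectangle height for \code{"loop"}, meters.
#' @return A \code{\link{tag_map}} (ids 0..count-1).
#' @export
make_tag_layout <- function(count, spacing = 1.3,
                            geometry = c("line", "loop"),
                            aisle_width = 2.6) {
  geometry <- match.arg(geometry)
  if (count < 2) stop("need at least two tags", call. = FALSE)
  if (spacing <= 0) stop("spacing must be positive", call. = FALSE)
  ids <- 0:(count - 1)
  if (geometry == "line") {
    tags <- data.frame(id = ids, x = ids * spacing, y = 0, theta = 0,
                       virtual = FALSE)
  } else {
    perimeter <- count * spacing
    if (perimeter <= 2 * aisle_width)
      stop("loop too short for the aisle width", call. = FALSE)
    len <- (perimeter - 2 * aisle_width) / 2
    corners <- cumsum(c(len, aisle_width, len, aisle_width))
    dirs <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
    headings <- c(0, pi / 2, pi, -pi / 2)
    pos <- t(vapply(ids * spacing, function(s) {
      seg <- findInterval(s, corners) + 1L  # s < perimeter, so seg in 1..4
      s0 <- if (seg == 1) 0 else corners[seg - 1]
      origin <- if (seg == 1) c(0, 0) else
        colSums(dirs[seq_len(seg - 1), , drop = FALSE] *
                  c(len, aisle_width, len, aisle_width)[seq_len(seg - 1)])
      c(origin + (s - s0) * dirs[seg, ], headings[seg])
    }, numeric(3)))
    tags <- data.frame(id = ids, x = pos[, 1], y = pos[, 2], theta = pos[, 3],
                       virtual = FALSE)
  }
  edges <- data.frame(from = ids[-count], to = ids[-1])
  if (geometry == "loop")
    edges <- rbind(edges, data.frame(from = count - 1L, to = 0L))
  tag_map(tags, edges)
}

#' Simulate a drive along a tag route
#'
#' Differential-drive kinematics along straight legs between route tags,
#' spinning in place at heading changes. Ground truth is exact; the
#' returned sensor log carries the true wheel/IMU increments perturbed by
#' the noise model, and a tag observation (nearest tag within detection
#' range, with seeded pose noise) at every sample where one is visible.
#' With zero noise, dead reckoning the log reproduces the ground truth.
#'
#' @param map a \code{\link{tag_map}} (ground truth).
#' @param route integer vector of tag ids to visit in order (>= 2).
#' @param speed platform speed on straight legs, m/s (> 0).
#' @param dt sample interval, seconds.
#' @param noise a \code{\link{noise_model}}.
#' @param seed integer seed; identical (inputs, seed) give identical
#'   output.
#' @param track_width wheel separation, meters.
#' @param turn_rate spin-in-place rate, rad/s.
#' @return list(log = \code{\link{sensor_log}}, truth = data.frame(t, x,
#'   y, theta)).
#' @export
simulate_drive <- function(map, route, speed = 0.3, dt = 0.05,
                           noise = noise_model(), seed = NULL,
                           track_width = 0.4, turn_rate = pi / 4) {
  stopifnot(inherits(map, "tag_map"), inherits(noise, "noise_model"))
  if (length(route) < 2) stop("route needs at least two tags", call. = FALSE)
  if (!all(route %in% map$tags$id))
    stop("route visits a tag absent from the map", call. = FALSE)
  if (speed <= 0 || speed * dt <= 0 || turn_rate <= 0)
    stop("infeasible speed profile", call. = FALSE)

  # plan true per-step increments (dsl, dsr, dtheta)
  steps <- list()
  pose <- tag_pose(map, route[1])
  heading <- pose[["theta"]]
  xy <- c(pose[["x"]], pose[["y"]])
  for (leg in seq_len(length(route) - 1)) {
    to <- tag_pose(map, route[leg + 1])
    vec <- c(to[["x"]] - xy[1], to[["y"]] - xy[2])
    dist <- sqrt(sum(vec^2))
    if (dist < 1e-12) next
    want <- atan2(vec[2], vec[1])
    turn <- wrap_angle(want - heading)
    if (abs(turn) > 1e-12) {
      n <- max(1L, ceiling(abs(turn) / (turn_rate * dt)))
      dth <- turn / n
      steps[[length(steps) + 1]] <-
        cbind(dsl = rep(-dth * track_width / 2, n),
              dsr = rep(dth * track_width / 2, n), dtheta = rep(dth, n))
      heading <- wrap_angle(heading + turn)
    }
    n <- max(1L, ceiling(dist / (speed * dt)))
    ds <- dist / n
    steps[[length(steps) + 1]] <-
      cbind(dsl = rep(ds, n), dsr = rep(ds, n), dtheta = rep(0, n))
    xy <- xy + vec
  }
  inc <- do.call(rbind, steps)
  n <- nrow(inc)
  t <- seq_len(n) * dt

  # integrate true trajectory (pre-update heading, as dead reckoning does)
  start <- tag_pose(map, route[1])
  tx <- ty <- tth <- numeric(n + 1)
  tx[1] <- start[["x"]]; ty[1] <- start[["y"]]; tth[1] <- start[["theta"]]
  for (k in seq_len(n)) {
    ds <- (inc[k, "dsl"] + inc[k, "dsr"]) / 2
    tx[k + 1] <- tx[k] + ds * cos(tth[k])
    ty[k + 1] <- ty[k] + ds * sin(tth[k])
    tth[k + 1] <- tth[k] + inc[k, "dtheta"]
  }

  real_tags <- map$tags[!map$tags$virtual, , drop = FALSE]
  with_seed(seed, {
    dsl <- inc[, "dsl"] + stats::rnorm(n, 0, noise$encoder_sd_per_m * abs(inc[, "dsl"]))
    dsr <- inc[, "dsr"] + stats::rnorm(n, 0, noise$encoder_sd_per_m * abs(inc[, "dsr"]))
    dth <- inc[, "dtheta"] + noise$imu_bias * dt +
      if (noise$imu_sd > 0) stats::rnorm(n, 0, noise$imu_sd) else 0
    obs <- vector("list", n)
    for (k in seq_len(n)) {
      d2 <- (real_tags$x - tx[k + 1])^2 + (real_tags$y - ty[k + 1])^2
      j <- which.min(d2)
      if (d2[j] <= noise$tag_range^2) {
        robot <- pose2d(tx[k + 1], ty[k + 1], tth[k + 1])
        rel <- pose_between(robot, pose2d(real_tags$x[j], real_tags$y[j],
                                          real_tags$theta[j]))
        obs[[k]] <- data.frame(
          t = t[k], id = real_tags$id[j],
          rel_x = rel[["x"]] + stats::rnorm(1, 0, noise$obs_trans_sd),
          rel_y = rel[["y"]] + stats::rnorm(1, 0, noise$obs_trans_sd),
          rel_theta = wrap_angle(rel[["theta"]] +
                                   stats::rnorm(1, 0, noise$obs_rot_sd)))
      }
    }
    observations <- do.call(rbind, obs[!vapply(obs, is.null, logical(1))])
    if (is.null(observations))
      observations <- data.frame(t = numeric(), id = integer(),
                                 rel_x = numeric(), rel_y = numeric(),
                                 rel_theta = numeric())
    log <- sensor_log(
      samples = data.frame(t = t, dsl = dsl, dsr = dsr, dtheta = dth),
      observations = observations)
    list(log = log,
         truth = data.frame(t = c(t[1] - dt, t), x = tx, y = ty,
                            theta = wrap_angle(tth)))
  })
}

#' Render a fruit detection stream along an aisle pass
#'
#' The camera faces the growing row (+y) while the platform travels +x at
#' constant speed. Each spherical fruit projects through the pinhole
#' model, \code{u = cx + fx * (x_f - x_r) / Z}, so fruit on a row at
#' triple the distance produce boxes a third the size — the geometry the
#' distance filtration exploits — and a fruit's center crosses the image
#' in \code{width * Z * fps / (fx * v)} frames, the quantity the keyframe
#' schedule divides into r parts. Detector noise (false negatives, false
#' positives, label flips, bbox jitter) is applied per the noise model.
#'
#' @param fruit data.frame with columns \code{x} (position along the
#'   aisle, m), \code{dist} (camera-to-fruit distance Z, m), \code{z}
#'   (height offset from the optical axis, m), \code{ripe} (logical) and
#'   optionally \code{row} (1 = target row).
#' @param camera a \code{\link{camera_model}}.
#' @param speed platform speed, m/s.
#' @param x_range numeric length-2: camera x at the first and last frame.
#' @param noise a \code{\link{noise_model}}.
#' @param seed integer seed.
#' @param fruit_radius sphere radius for bbox projection, meters.
#' @return A \code{\link{detection_stream}}; attribute
#'   \code{"ground_truth"} is a list with \code{ripe} / \code{unripe}
#'   counts of target-row fruit whose center enters the image, and
#'   \code{visible_ids}, the row indices of \code{fruit} that appear.
#' @export
render_detection_stream <- function(fruit, camera, speed, x_range,
                                    noise = noise_model(), seed = NULL,
                                    fruit_radius = 0.015) {
  stopifnot(is.data.frame(fruit), inherits(camera, "camera_model"),
            inherits(noise, "noise_model"))
  need <- c("x", "dist", "z", "ripe")
  if (!all(need %in% names(fruit)))
    stop("fruit needs columns x, dist, z, ripe", call. = FALSE)
  if (is.null(fruit$row)) fruit$row <- 1L
  if (any(fruit$dist <= 0)) stop("fruit dist must be positive", call. = FALSE)
  if (speed <= 0) stop("speed must be positive", call. = FALSE)
  n_frames <- max(1L, floor((x_range[2] - x_range[1]) / speed * camera$fps) + 1L)

  nf <- nrow(fruit)
  halfw <- camera$fx * fruit_radius / fruit$dist
  halfh <- camera$fy * fruit_radius / fruit$dist
  vc <- camera$cy - camera$fy * fruit$z / fruit$dist
  visible_any <- rep(FALSE, nf)

  frames <- 0:(n_frames - 1)
  xr <- x_range[1] + speed * frames / camera$fps
  rows <- vector("list", n_frames)
  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      uc <- camera$cx + camera$fx * (fruit$x - xr[k]) / fruit$dist
      xmin <- uc - halfw; xmax <- uc + halfw
      ymin <- vc - halfh; ymax <- vc + halfh
      vis <- xmax > 0 & xmin < camera$width & ymax > 0 & ymin < camera$height
      visible_any <- visible_any | (uc >= 0 & uc < camera$width & vis)
      idx <- which(vis)
      if (noise$fn_rate > 0 && length(idx))
        idx <- idx[stats::runif(length(idx)) >= noise$fn_rate]
      det <- if (length(idx)) {
        lab <- ifelse(fruit$ripe[idx], "ripe", "unripe")
        if (noise$flip_prob > 0) {
          fl <- stats::runif(length(idx)) < noise$flip_prob
          lab[fl] <- ifelse(lab[fl] == "ripe", "unripe", "ripe")
        }
        d <- data.frame(frame = frames[k], label = lab, confidence = 0.99,
                        xmin = xmin[idx], ymin = ymin[idx],
                        xmax = xmax[idx], ymax = ymax[idx])
        if (noise$bbox_jitter_sd > 0) {
          for (col in c("xmin", "ymin", "xmax", "ymax"))
            d[[col]] <- d[[col]] + stats::rnorm(nrow(d), 0, noise$bbox_jitter_sd)
          d <- d[d$xmin < d$xmax & d$ymin < d$ymax, , drop = FALSE]
        }
        d
      } else NULL
      if (noise$fp_rate > 0 && stats::runif(1) < noise$fp_rate) {
        bw <- 2 * mean(halfw); bh <- 2 * mean(halfh)
        x0 <- stats::runif(1, 0, camera$width - bw)
        y0 <- stats::runif(1, 0, camera$height - bh)
        fp <- data.frame(frame = frames[k],
                         label = if (stats::runif(1) < 0.5) "ripe" else "unripe",
                         confidence = 0.5, xmin = x0, ymin = y0,
                         xmax = x0 + bw, ymax = y0 + bh)
        det <- rbind(det, fp)
      }
      if (!is.null(det) && nrow(det)) {
        det$xmin <- pmax(det$xmin, 0); det$ymin <- pmax(det$ymin, 0)
        det$xmax <- pmin(det$xmax, camera$width)
        det$ymax <- pmin(det$ymax, camera$height)
        det <- det[det$xmin < det$xmax & det$ymin < det$ymax, , drop = FALSE]
        rows[[k]] <- det
      }
    }
    det_all <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(det_all)) det_all <- empty_detections()
    stream <- detection_stream(camera, speed, det_all, n_frames = n_frames)
    target <- visible_any & fruit$row == 1L
    attr(stream, "ground_truth") <- list(
      ripe = sum(target & fruit$ripe),
      unripe = sum(target & !fruit$ripe),
      visible_ids = which(visible_any))
    stream
  })
}

#' Random fruit scene for the simulator
#'
#' Fruit scattered uniformly along an aisle segment on the target row
#' (and optionally a farther distractor row), at the stated
#' camera-to-fruit distances.
#'
#' @param n_ripe,n_unripe target-row fruit counts.
#' @param n_far distractor fruit on the far row.
#' @param x_range aisle extent occupied by fruit, meters.
#' @param dist target-row camera-to-fruit distance, m.
#' @param far_dist distractor-row distance, m.
#' @param z_spread half-range of vertical scatter about the optical
#'   axis, m.
#' @param seed integer seed.
#' @return Fruit data.frame for
#'   \code{\link{render_detection_stream}}.
#' @export
make_fruit_scene <- function(n_ripe, n_unripe = 0, n_far = 0,
                             x_range = c(0, 10), dist = 0.41,
                             far_dist = 3 * dist, z_spread = 0.08,
                             seed = NULL) {
  with_seed(seed, {
    n <- n_ripe + n_unripe + n_far
    data.frame(
      x = stats::runif(n, x_range[1], x_range[2]),
      dist = c(rep(dist, n_ripe + n_unripe), rep(far_dist, n_far)),
      z = stats::runif(n, -z_spread, z_spread),
      ripe = c(rep(TRUE, n_ripe), rep(FALSE, n_unripe),
               stats::runif(n_far) < 0.5),
      row = c(rep(1L, n_ripe + n_unripe), rep(2L, n_far)))
  })
}

#' Full synthetic world specification
#'
#' Bundles the tag layout, fruit scene, camera, platform speed and noise
#' model; \code{\link{simulate_world}} turns it into the sensor log and
#' detection stream every other module consumes. Defaults emulate the
#' study conditions: 45 tags spaced 1.3 m on a closed inspection loop, a
#' 1280x720 camera at 29.72 fps, fruit about 0.41 m from the camera,
#' platform speeds 0.2-0.4 m/s.
#'
#' @param tag_count,tag_spacing,geometry,aisle_width layout parameters
#'   (see \code{\link{make_tag_layout}}).
#' @param fruit fruit scene data.frame (see
#'   \code{\link{make_fruit_scene}}).
#' @param camera a \code{\link{camera_model}}.
#' @param speed platform speed, m/s.
#' @param noise a \code{\link{noise_model}}.
#' @param seed integer seed; (spec, seed) determines every output.
#' @return An object of class \code{world_spec}.
#' @export
world_spec <- function(tag_count = 45, tag_spacing = 1.3,
                       geometry = "loop", aisle_width = 2.6,
                       fruit = make_fruit_scene(40, 20, seed = 1),
                       camera = camera_model(), speed = 0.3,
                       noise = noise_model(), seed = 1) {
  structure(list(tag_count = tag_count, tag_spacing = tag_spacing,
                 geometry = geometry, aisle_width = aisle_width,
                 fruit = fruit, camera = camera, speed = speed,
                 noise = noise, seed = seed),
            class = "world_spec")
}

#' Simulate a complete inspection run
#'
#' Builds the ground-truth tag map, drives the closed route (all tags and
#' back to tag 0), and renders the detection stream of the first-aisle
#' pass.
#'
#' @param spec a \code{\link{world_spec}}.
#' @return list(map, log, truth, stream).
#' @export
simulate_world <- function(spec) {
  stopifnot(inherits(spec, "world_spec"))
  map <- make_tag_layout(spec$tag_count, spec$tag_spacing, spec$geometry,
                         spec$aisle_width)
  route <- c(map$tags$id, map$tags$id[1])
  drv <- simulate_drive(map, route, speed = spec$speed, noise = spec$noise,
                        seed = spec$seed)
  stream <- render_detection_stream(
    spec$fruit, spec$camera, spec$speed,
    x_range = range(spec$fruit$x) + c(-1, 1), noise = spec$noise,
    seed = spec$seed + 1L)
  list(map = map, log = drv$log, truth = drv$truth, stream = stream)
}
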