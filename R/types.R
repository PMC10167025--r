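#' Pinhole camera model
#'
#' Intrinsics of the inspection camera. Image coordinates are 0-based,
#' origin top-left, x rightward; bounding boxes are half-open
#' [xmin, xmax) x [ymin, ymax) in pixels.
#'
#' @param fx,fy focal lengths, pixels.
#' @param cx,cy principal point, pixels.
#' @param width,height frame size, pixels.
#' @param fps frame rate, frames/second. The default is the recorded rate
#'   of the platform's RealSense stream (nominally 30 fps).
#' @return An object of class \code{camera_model}.
#' @export
camera_model <- function(fx = 900, fy = 900, cx = 640, cy = 360,
                         width = 1280, height = 720, fps = 29.72) {
  vals <- c(fx = fx, fy = fy, cx = cx, cy = cy,
            width = width, height = height, fps = fps)
  if (any(!is.finite(vals)) || any(vals[c("fx", "fy", "width", "height", "fps")] <= 0))
    stop("camera_model(): fx, fy, width, height, fps must be positive and finite",
         call. = FALSE)
  structure(as.list(vals), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %dx%d px, fx = %.1f, fy = %.1f, %.2f fps\n",
              x$width, x$height, x$fx, x$fy, x$fps))
  invisible(x)
}

detection_columns <- c("frame", "label", "confidence",
                       "xmin", "ymin", "xmax", "ymax")

empty_detections <- function() {
  data.frame(frame = integer(), label = character(),
             confidence = numeric(), xmin = numeric(), ymin = numeric(),
             xmax = numeric(), ymax = numeric())
}

validate_detections <- function(det, camera, where = "detections") {
  stopifnot(is.data.frame(det))
  missing <- setdiff(detection_columns, names(det))
  if (length(missing))
    stop(sprintf("%s: missing columns: %s", where,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(det) == 0) return(invisible(det))
  bad <- which(det$xmin >= det$xmax | det$ymin >= det$ymax)
  if (length(bad))
    stop(sprintf("%s: degenerate bbox (xmin >= xmax or ymin >= ymax) at frame %d",
                 where, det$frame[bad[1]]), call. = FALSE)
  oob <- which(det$xmin < 0 | det$ymin < 0 |
               det$xmax > camera$width | det$ymax > camera$height)
  if (length(oob))
    stop(sprintf("%s: bbox outside the %dx%d frame at frame %d",
                 where, camera$width, camera$height, det$frame[oob[1]]),
         call. = FALSE)
  if (any(det$frame < 0))
    stop(sprintf("%s: negative frame index", where), call. = FALSE)
  if (!all(det$label %in% c("ripe", "unripe")))
    stop(sprintf("%s: labels must be 'ripe' or 'unripe'", where), call. = FALSE)
  if (any(det$confidence < 0 | det$confidence > 1))
    stop(sprintf("%s: confidence outside [0, 1]", where), call. = FALSE)
  invisible(det)
}

#' Frame-indexed fruit detection stream
#'
#' The input to the counting pipeline: per-frame ripe/unripe bounding
#' boxes from an (external) detector, together with the camera model and
#' the constant platform speed at which the video was recorded. Frames
#' are indexed 0..n_frames-1; frames without detections are implicit.
#'
#' @param camera a \code{\link{camera_model}}.
#' @param speed platform traveling speed, m/s; must be > 0.
#' @param detections data.frame with columns \code{frame}, \code{label}
#'   ("ripe"/"unripe"), \code{confidence}, \code{xmin}, \code{ymin},
#'   \code{xmax}, \code{ymax}.
#' @param n_frames total number of frames in the video (>= 1 + max frame
#'   index carrying a detection).
#' @return An object of class \code{detection_stream}.
#' @export
detection_stream <- function(camera, speed, detections = empty_detections(),
                             n_frames = if (nrow(detections)) max(detections$frame) + 1L else 0L) {
  stopifnot(inherits(camera, "camera_model"))
  if (!is.numeric(speed) || length(speed) != 1 || !is.finite(speed) || speed <= 0)
    stop("detection_stream(): speed must be a positive scalar (m/s)", call. = FALSE)
  validate_detections(detections, camera)
  n_frames <- as.integer(n_frames)
  if (nrow(detections) && n_frames < max(detections$frame) + 1L)
    stop("detection_stream(): n_frames smaller than the largest frame index",
         call. = FALSE)
  detections <- detections[order(detections$frame), , drop = FALSE]
  rownames(detections) <- NULL
  structure(list(camera = camera, speed = speed,
                 detections = detections, n_frames = n_frames),
            class = "detection_stream")
}

#' @export
print.detection_stream <- function(x, ...) {
  cat(sprintf("<detection_stream> %d frames @ %.2f fps, v = %.2f m/s, %d detections (%d ripe)\n",
              x$n_frames, x$camera$fps, x$speed, nrow(x$detections),
              sum(x$detections$label == "ripe")))
  invisible(x)
}

#' Wheel-encoder / IMU sensor log with tag observations
#'
#' Time-ordered odometric increments plus the fiducial observations used
#' for mapping and localization. \code{samples} carries per-interval left
#' and right wheel displacements (m) and the IMU heading increment (rad);
#' \code{observations} carries the pose of a detected tag expressed in
#' the robot frame.
#'
#' @param samples data.frame with columns \code{t}, \code{dsl},
#'   \code{dsr}, \code{dtheta}; timestamps non-decreasing.
#' @param observations data.frame with columns \code{t}, \code{id},
#'   \code{rel_x}, \code{rel_y}, \code{rel_theta}; ids >= 0.
#' @return An object of class \code{sensor_log}.
#' @export
sensor_log <- function(samples = data.frame(t = numeric(), dsl = numeric(),
                                            dsr = numeric(), dtheta = numeric()),
                       observations = data.frame(t = numeric(), id = integer(),
                                                 rel_x = numeric(), rel_y = numeric(),
                                                 rel_theta = numeric())) {
  stopifnot(is.data.frame(samples), is.data.frame(observations))
  need_s <- c("t", "dsl", "dsr", "dtheta")
  need_o <- c("t", "id", "rel_x", "rel_y", "rel_theta")
  if (!all(need_s %in% names(samples)))
    stop("sensor_log(): samples needs columns t, dsl, dsr, dtheta", call. = FALSE)
  if (!all(need_o %in% names(observations)))
    stop("sensor_log(): observations needs columns t, id, rel_x, rel_y, rel_theta",
         call. = FALSE)
  if (nrow(samples) && is.unsorted(samples$t))
    stop("sensor_log(): sample timestamps must be non-decreasing", call. = FALSE)
  if (nrow(observations) && is.unsorted(observations$t))
    stop("sensor_log(): observation timestamps must be non-decreasing", call. = FALSE)
  if (!all(is.finite(as.matrix(samples[need_s]))))
    stop("sensor_log(): non-finite sample values", call. = FALSE)
  if (nrow(observations) && any(observations$id < 0))
    stop("sensor_log(): tag ids must be >= 0", call. = FALSE)
  structure(list(samples = samples, observations = observations),
            class = "sensor_log")
}

#' @export
print.sensor_log <- function(x, ...) {
  cat(sprintf("<sensor_log> %d odometry samples, %d tag observations of %d tags\n",
              nrow(x$samples), nrow(x$observations),
              length(unique(x$observations$id))))
  invisible(x)
}

#' Tag map
#'
#' Global planar poses of the ground fiducials plus the undirected
#' adjacency between consecutive route tags; the object produced by
#' mapping and consumed by localization and path planning. Virtual tags
#' (temporary waypoints splitting an edge) are flagged and must have
#' exactly two neighbors.
#'
#' @param tags data.frame with columns \code{id}, \code{x}, \code{y},
#'   \code{theta}, \code{virtual} (logical).
#' @param edges data.frame with columns \code{from}, \code{to} (tag ids);
#'   stored undirected.
#' @return An object of class \code{tag_map}.
#' @export
tag_map <- function(tags = data.frame(id = integer(), x = numeric(),
                                      y = numeric(), theta = numeric(),
                                      virtual = logical()),
                    edges = data.frame(from = integer(), to = integer())) {
  stopifnot(is.data.frame(tags), is.data.frame(edges))
  if (!all(c("id", "x", "y", "theta") %in% names(tags)))
    stop("tag_map(): tags needs columns id, x, y, theta", call. = FALSE)
  if (is.null(tags$virtual)) tags$virtual <- rep(FALSE, nrow(tags))
  if (anyDuplicated(tags$id))
    stop(sprintf("tag_map(): duplicate tag id %d",
                 tags$id[duplicated(tags$id)][1]), call. = FALSE)
  if (!all(c("from", "to") %in% names(edges)))
    stop("tag_map(): edges needs columns from, to", call. = FALSE)
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$from, edges$to)), tags$id)
    if (length(unknown))
      stop(sprintf("tag_map(): edge references unknown tag id %d", unknown[1]),
           call. = FALSE)
    # canonical undirected storage: from < to, no duplicates, no self loops
    if (any(edges$from == edges$to))
      stop("tag_map(): self-loop edge", call. = FALSE)
    lo <- pmin(edges$from, edges$to); hi <- pmax(edges$from, edges$to)
    edges <- unique(data.frame(from = lo, to = hi))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  tags$theta <- wrap_angle(tags$theta)
  tags <- tags[order(tags$id), c("id", "x", "y", "theta", "virtual")]
  rownames(tags) <- NULL
  m <- structure(list(tags = tags, edges = edges), class = "tag_map")
  for (vid in tags$id[tags$virtual]) {
    if (length(tag_neighbors(m, vid)) != 2L)
      stop(sprintf("tag_map(): virtual tag %d must have exactly two neighbors", vid),
           call. = FALSE)
  }
  m
}

#' @export
print.tag_map <- function(x, ...) {
  cat(sprintf("<tag_map> %d tags (%d virtual), %d edges\n",
              nrow(x$tags), sum(x$tags$virtual), nrow(x$edges)))
  invisible(x)
}

#' Pose of a tag in the map
#' @param map a \code{\link{tag_map}}.
#' @param id tag id.
#' @return A \code{\link{pose2d}}.
#' @export
tag_pose <- function(map, id) {
  stopifnot(inherits(map, "tag_map"))
  i <- match(id, map$tags$id)
  if (is.na(i))
    stop(sprintf("tag %d is not in the map", id), call. = FALSE)
  pose2d(map$tags$x[i], map$tags$y[i], map$tags$theta[i])
}

#' Neighbors of a tag on the route graph
#' @inheritParams tag_pose
#' @return Integer vector of neighboring tag ids.
#' @export
tag_neighbors <- function(map, id) {
  stopifnot(inherits(map, "tag_map"))
  e <- map$edges
  sort(unique(c(e$to[e$from == id], e$from[e$to == id])))
}
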