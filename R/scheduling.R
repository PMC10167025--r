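# Keyframe-interval scheduling for counting-from-video.
#
# Every fruit drifts across the image as the platform moves at constant
# speed v past the growing row. If keyframes are spaced dp = w/r pixels of
# apparent motion apart, each fruit appears in exactly r keyframes and the
# raw detection total divided by r estimates the fruit count. The frame
# interval realising dp is i_t = dp * d * fps / (fx * v), which must be
# rounded to an integer i; the rounding error e = |i_t - i| is what the
# sequence-selection step minimises.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Pixel distance between neighboring keyframes
#'
#' The apparent motion between consecutive keyframes when each fruit is to
#' be seen in exactly \code{r} keyframes: \code{width / r}. Every fruit
#' must appear at least twice, so \code{r >= 2}.
#'
#' @param camera a \code{\link{camera_model}}.
#' @param r repetition count (integer >= 2).
#' @return Pixel distance, \code{camera$width / r}.
#' @export
keyframe_pixel_distance <- function(camera, r) {
  stopifnot(inherits(camera, "camera_model"))
  if (any(r < 2)) stop("r must be >= 2 (every fruit must appear at least twice)",
                       call. = FALSE)
  camera$width / r
}

#' Theoretical keyframe interval
#'
#' Frame interval (real-valued) giving a keyframe pixel spacing of
#' \code{width/r} for fruit at camera distance \code{d} passing at platform
#' speed \code{v}: \code{(width/r) * d * fps / (fx * v)}. Depends on v and
#' r only through their product.
#'
#' @inheritParams keyframe_pixel_distance
#' @param v platform speed, m/s (> 0).
#' @param d camera-to-fruit distance, meters (> 0); treated as constant
#'   for the whole row.
#' @return Theoretical interval in frames (real).
#' @export
theoretical_interval <- function(camera, v, d, r) {
  stopifnot(inherits(camera, "camera_model"))
  if (any(v <= 0)) stop("v must be positive", call. = FALSE)
  if (any(d <= 0)) stop("d must be positive", call. = FALSE)
  keyframe_pixel_distance(camera, r) * d * camera$fps / (camera$fx * v)
}

#' Actual (integer) keyframe interval
#'
#' Nearest integer to the theoretical interval; half-ties round away from
#' zero. An interval below 1 frame cannot be realised and is rejected.
#'
#' @param i_t theoretical interval, frames (> 0).
#' @return Integer interval.
#' @export
actual_interval <- function(i_t) {
  if (any(i_t <= 0)) stop("theoretical interval must be positive", call. = FALSE)
  i <- as.integer(round_half_away(i_t))
  if (any(i < 1))
    stop("rounded keyframe interval < 1 frame; reduce speed or repetitions",
         call. = FALSE)
  i
}

#' Keyframe extraction error
#'
#' Absolute rounding error \code{|i_t - i|}, in frames; always in
#' [0, 0.5] when \code{i} is the nearest integer of \code{i_t}.
#'
#' @param i_t theoretical interval (real frames).
#' @param i actual interval (integer frames).
#' @return Extraction error, dimensionless.
#' @export
extraction_error <- function(i_t, i) abs(i_t - i)

#' Calibrate the fruit distance from one observed interval
#'
#' The schedule depends on camera intrinsics and scene only through the
#' constant \code{fx * d}. Given one known theoretical interval (e.g.
#' measured at r = 2), returns the \code{d} consistent with it for the
#' given camera, so subsequent schedules reproduce the whole interval
#' table at any (v, r).
#'
#' @inheritParams theoretical_interval
#' @param i_t_ref observed theoretical interval at \code{(r, v)}.
#' @return Fruit distance d in meters.
#' @export
calibrate_fruit_distance <- function(camera, v, r, i_t_ref) {
  stopifnot(inherits(camera, "camera_model"))
  if (i_t_ref <= 0) stop("reference interval must be positive", call. = FALSE)
  i_t_ref * r * camera$fx * v / (camera$width * camera$fps)
}

#' Counting pipeline configuration
#'
#' Thresholds and geometry for the yield-monitoring pipeline. Defaults
#' follow the published operating point: repetitions r = 2..15, keyframe
#' sequences kept only if their extraction error is small or their
#' interval not too short (e <= 0.1 or i >= 4 frames).
#'
#' @param fruit_distance camera-to-fruit distance d, meters (constant per
#'   row).
#' @param r_max largest repetition count considered (>= 2).
#' @param error_threshold extraction-error threshold e_s (dimensionless).
#' @param interval_threshold interval threshold i_s, frames.
#' @param min_bbox_area distance-filtration cutoff, square pixels;
#'   detections with smaller boxes (far-row fruit) are dropped. 0 disables.
#' @param edge_margin edge-filtration margin, pixels.
#' @param counted_edge image edge at which a boundary-straddling fruit is
#'   counted; detections touching the opposite edge are dropped.
#' @return An object of class \code{counting_config}.
#' @export
counting_config <- function(fruit_distance, r_max = 15L,
                            error_threshold = 0.1, interval_threshold = 4L,
                            min_bbox_area = 0, edge_margin = 5,
                            counted_edge = c("left", "right")) {
  counted_edge <- match.arg(counted_edge)
  if (r_max < 2) stop("r_max must be >= 2", call. = FALSE)
  if (error_threshold <= 0) stop("error_threshold must be > 0", call. = FALSE)
  if (interval_threshold < 1) stop("interval_threshold must be >= 1", call. = FALSE)
  if (fruit_distance <= 0) stop("fruit_distance must be > 0", call. = FALSE)
  if (min_bbox_area < 0) stop("min_bbox_area must be >= 0", call. = FALSE)
  if (edge_margin < 0) stop("edge_margin must be >= 0", call. = FALSE)
  structure(list(fruit_distance = fruit_distance, r_max = as.integer(r_max),
                 error_threshold = error_threshold,
                 interval_threshold = as.integer(interval_threshold),
                 min_bbox_area = min_bbox_area, edge_margin = edge_margin,
                 counted_edge = counted_edge),
            class = "counting_config")
}

#' Keyframe schedules for all candidate repetition counts
#'
#' One schedule per r in 2..r_max: keyframe pixel spacing d_p, theoretical
#' interval i_t, nearest-integer interval i and extraction error e.
#'
#' @inheritParams theoretical_interval
#' @param config a \code{\link{counting_config}} (supplies d and r_max).
#' @return data.frame with columns \code{r}, \code{d_p}, \code{i_t},
#'   \code{i}, \code{e}, one row per r.
#' @export
plan_sequences <- function(camera, v, config) {
  stopifnot(inherits(config, "counting_config"))
  r <- 2:config$r_max
  i_t <- theoretical_interval(camera, v, config$fruit_distance, r)
  i <- actual_interval(i_t)
  data.frame(r = r, d_p = keyframe_pixel_distance(camera, r),
             i_t = i_t, i = i, e = extraction_error(i_t, i))
}

#' Select the keyframe sequences used for counting
#'
#' Drops schedules whose extraction error exceeds \code{error_threshold}
#' AND whose interval is below \code{interval_threshold} (large rounding
#' error on a short interval distorts counts most). The survivors are
#' sorted by extraction error; the best three are kept, or only the best
#' two when the third-smallest error still exceeds the threshold. Ties in
#' e prefer larger r (more repetitions average out detector noise).
#'
#' @param plans data.frame from \code{\link{plan_sequences}}.
#' @param config a \code{\link{counting_config}}.
#' @return The selected rows of \code{plans}, sorted by ascending e.
#' @export
select_sequences <- function(plans, config) {
  stopifnot(is.data.frame(plans), nrow(plans) >= 2,
            inherits(config, "counting_config"))
  drop <- plans$e > config$error_threshold & plans$i < config$interval_threshold
  keep <- plans[!drop, , drop = FALSE]
  if (nrow(keep) < 2)
    stop("fewer than two keyframe schedules survive filtering; try a different platform speed",
         call. = FALSE)
  keep <- keep[order(keep$e, -keep$r), , drop = FALSE]
  n_keep <- if (nrow(keep) >= 3 && keep$e[3] <= config$error_threshold) 3L else 2L
  out <- utils::head(keep, n_keep)
  rownames(out) <- NULL
  out
}
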