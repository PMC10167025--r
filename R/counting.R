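# Counting stage: keyframe extraction, detection filtration, per-sequence
# counts and the multi-sequence average.

#' Extract keyframe indices
#'
#' Positions 0, i, 2i, ... of the stream's frame list (frame indices,
#' 0-based). An empty stream yields an empty sequence.
#'
#' @param stream a \code{\link{detection_stream}}.
#' @param i keyframe interval, frames (integer >= 1).
#' @return Integer vector of keyframe frame indices.
#' @export
extract_keyframes <- function(stream, i) {
  stopifnot(inherits(stream, "detection_stream"))
  if (i < 1) stop("keyframe interval must be >= 1", call. = FALSE)
  if (stream$n_frames == 0L) return(integer())
  seq.int(0L, stream$n_frames - 1L, by = as.integer(i))
}

#' Distance filtration
#'
#' Removes detections whose bounding-box area falls below
#' \code{config$min_bbox_area}: under the pinhole model, fruit on a
#' farther (non-target) growing row project to proportionally smaller
#' boxes, so a single area cutoff separates the rows. Order is preserved.
#'
#' @param detections detection data.frame (see
#'   \code{\link{detection_stream}}).
#' @param config a \code{\link{counting_config}}.
#' @return The detections that survive, same columns.
#' @export
distance_filter <- function(detections, config) {
  stopifnot(inherits(config, "counting_config"))
  if (nrow(detections) == 0 || config$min_bbox_area <= 0) return(detections)
  area <- (detections$xmax - detections$xmin) * (detections$ymax - detections$ymin)
  out <- detections[area >= config$min_bbox_area, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propose a distance-filtration cutoff from a calibration stream
#'
#' Bbox areas in a two-row scene are bimodal (near-row vs far-row fruit);
#' returns the midpoint between the two area modes found by 2-means on
#' log-area, a workable \code{min_bbox_area} for
#' \code{\link{distance_filter}}.
#'
#' @param detections detection data.frame with both rows visible.
#' @return Suggested area cutoff, square pixels.
#' @export
suggest_min_bbox_area <- function(detections) {
  area <- (detections$xmax - detections$xmin) * (detections$ymax - detections$ymin)
  if (length(area) < 2) stop("need at least two detections to calibrate", call. = FALSE)
  if (diff(range(area)) < .Machine$double.eps) return(min(area))
  km <- stats::kmeans(log(area), centers = range(log(area)))
  exp(mean(km$centers))
}

#' Edge filtration
#'
#' A fruit straddling the image boundary is visible (partially) at the
#' trailing edge of one keyframe and again at the leading edge r keyframes
#' later; counting it at both edges double-counts it. Detections whose box
#' reaches within \code{edge_margin} pixels of the non-counted edge are
#' dropped; boxes touching the counted edge (default left, the edge fruit
#' drift towards as the platform advances) are kept.
#'
#' @inheritParams distance_filter
#' @param camera the stream's \code{\link{camera_model}}.
#' @return The detections that survive, order preserved.
#' @export
edge_filter <- function(detections, camera, config) {
  stopifnot(inherits(camera, "camera_model"), inherits(config, "counting_config"))
  if (nrow(detections) == 0) return(detections)
  drop <- if (config$counted_edge == "left")
    detections$xmax >= camera$width - config$edge_margin
  else
    detections$xmin <= config$edge_margin
  out <- detections[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count ripe fruit in one keyframe sequence
#'
#' Total ripe-labeled detections across the (already filtered) keyframes,
#' divided by the repetition count r: with keyframes spaced width/r pixels
#' apart every fruit is seen r times, so the quotient estimates the fruit
#' count.
#'
#' @param keyframes detection data.frame restricted to the keyframes of
#'   one sequence, already filtered.
#' @param r repetition count (>= 2).
#' @return Real-valued per-sequence count n_r.
#' @export
count_sequence <- function(keyframes, r) {
  if (r < 2) stop("r must be >= 2", call. = FALSE)
  sum(keyframes$label == "ripe") / r
}

#' Average the per-sequence counts
#'
#' Arithmetic mean of the per-sequence counts, rounded to the nearest
#' integer (half away from zero) — the reported fruit count.
#'
#' @param n_r numeric vector of per-sequence counts (non-empty).
#' @return Integer count n.
#' @export
multi_sequence_average <- function(n_r) {
  if (length(n_r) == 0) stop("no per-sequence counts to average", call. = FALSE)
  as.integer(round_half_away(mean(n_r)))
}

#' Run the full yield-monitoring pipeline on a detection stream
#'
#' Plans keyframe schedules for r = 2..r_max
#' (\code{\link{plan_sequences}}), selects the 2-3 lowest-extraction-error
#' sequences (\code{\link{select_sequences}}), and for each: extracts
#' keyframes, applies distance then edge filtration, and counts ripe
#' detections divided by r. The final count is the rounded mean across
#' sequences.
#'
#' @param stream a \code{\link{detection_stream}} (non-empty).
#' @param config a \code{\link{counting_config}}.
#' @return An object of class \code{count_result}: list with \code{n}
#'   (final integer count), \code{selected} (the chosen schedules),
#'   \code{sequences} (per-sequence diagnostics: keyframes, detections
#'   surviving each filtration stage, n_r) and \code{per_keyframe}
#'   (kept ripe detections per keyframe per sequence).
#' @export
run_yield_monitoring <- function(stream, config) {
  stopifnot(inherits(stream, "detection_stream"), inherits(config, "counting_config"))
  if (stream$n_frames == 0L) stop("empty detection stream", call. = FALSE)
  plans <- plan_sequences(stream$camera, stream$speed, config)
  selected <- select_sequences(plans, config)

  seq_rows <- list(); audit <- list()
  for (s in seq_len(nrow(selected))) {
    r <- selected$r[s]; i <- selected$i[s]
    kf <- extract_keyframes(stream, i)
    det <- stream$detections[stream$detections$frame %in% kf, , drop = FALSE]
    after_dist <- distance_filter(det, config)
    after_edge <- edge_filter(after_dist, stream$camera, config)
    n_r <- count_sequence(after_edge, r)
    seq_rows[[s]] <- data.frame(
      r = r, i = i, e = selected$e[s], n_keyframes = length(kf),
      raw = nrow(det), removed_distance = nrow(det) - nrow(after_dist),
      removed_edge = nrow(after_dist) - nrow(after_edge),
      ripe_counted = sum(after_edge$label == "ripe"), n_r = n_r)
    ripe_kf <- after_edge[after_edge$label == "ripe", , drop = FALSE]
    audit[[s]] <- data.frame(
      r = r, frame = kf,
      ripe = as.vector(table(factor(ripe_kf$frame, levels = kf))))
  }
  sequences <- do.call(rbind, seq_rows)
  structure(list(n = multi_sequence_average(sequences$n_r),
                 selected = selected, sequences = sequences,
                 per_keyframe = do.call(rbind, audit)),
            class = "count_result")
}

#' @export
print.count_result <- function(x, ...) {
  cat(sprintf("<count_result> n = %d ripe fruit from %d sequences (r = %s)\n",
              x$n, nrow(x$sequences),
              paste(x$sequences$r, collapse = ", ")))
  print(x$sequences, row.names = FALSE)
  invisible(x)
}

#' Relative counting / yield error
#'
#' \code{err_c}: relative absolute error of the counter against the
#' detection-level ground truth (ripe fruit visible to the detector);
#' \code{err_y}: against the grower-annotated true ripe count. Both are
#' \code{|n - gt| / gt}, dimensionless; vectorised.
#'
#' @param n estimated count(s).
#' @param gt ground-truth count(s), > 0.
#' @return Relative error(s).
#' @export
err_c <- function(n, gt) {
  if (any(gt <= 0)) stop("ground-truth count must be positive", call. = FALSE)
  abs(n - gt) / gt
}

#' @rdname err_c
#' @export
err_y <- err_c
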