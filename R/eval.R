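# Positioning-accuracy metrics.

#' Root mean squared error
#'
#' \code{sqrt(mean(errors^2))}; rejects empty input.
#'
#' @param errors numeric vector of deviations (any unit).
#' @return RMSE in the same unit.
#' @export
rmse <- function(errors) {
  if (length(errors) == 0) stop("rmse(): empty input", call. = FALSE)
  sqrt(mean(errors^2))
}

#' Positioning accuracy over pooled trials
#'
#' PA is the RMSE of the Euclidean deviation pooled over every trial of
#' every target tag (the deviation between the commanded tag position and
#' the position actually reached).
#'
#' @param trials data.frame with a \code{tag_id} column and either an
#'   \code{err_d} column or both \code{err_x} and \code{err_y} (from
#'   which \code{err_d} is derived); deviations in millimeters.
#' @return Pooled PA in millimeters.
#' @export
positioning_accuracy <- function(trials) {
  summary <- positioning_summary(trials)
  attr(summary, "pa")
}

#' Per-tag RMSE table and pooled PA
#'
#' Arranges trial deviations the way positioning-accuracy tables are
#' reported: one row per target tag with its trial mean and RMSE, the
#' pooled PA over all trials attached as attribute \code{"pa"}.
#'
#' @inheritParams positioning_accuracy
#' @return data.frame (tag_id, n, mean, rmse) with attribute \code{pa}.
#' @export
positioning_summary <- function(trials) {
  stopifnot(is.data.frame(trials), "tag_id" %in% names(trials))
  if (!"err_d" %in% names(trials)) {
    if (!all(c("err_x", "err_y") %in% names(trials)))
      stop("trials need err_d, or err_x and err_y", call. = FALSE)
    trials$err_d <- sqrt(trials$err_x^2 + trials$err_y^2)
  }
  if (nrow(trials) == 0) stop("no trials", call. = FALSE)
  tags <- unique(trials$tag_id)
  out <- data.frame(
    tag_id = tags,
    n = vapply(tags, function(id) sum(trials$tag_id == id), integer(1)),
    mean = vapply(tags, function(id) mean(trials$err_d[trials$tag_id == id]),
                  numeric(1)),
    rmse = vapply(tags, function(id) rmse(trials$err_d[trials$tag_id == id]),
                  numeric(1)))
  attr(out, "pa") <- rmse(trials$err_d)
  out
}
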