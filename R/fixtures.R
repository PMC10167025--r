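# Bundled benchmark tables from the field study the package models:
# per-tag positioning deviations of repeated navigation trials, and the
# per-setup ripe-fruit counts of eight inspection videos under every
# candidate keyframe schedule. They serve as fixed inputs for the metric
# arithmetic (RMSE / positioning accuracy, relative counting error) and
# for validating the schedule selection rule.

#' Benchmark measurement tables
#'
#' Returns the fixed benchmark tables shipped with the package:
#' \describe{
#'   \item{positioning_d}{Euclidean positioning deviations (mm): 5 trials
#'     for each of target tags 8, 12 and 21.}
#'   \item{positioning_x, positioning_y}{the same trials decomposed along
#'     the aisle (x) and across it (y).}
#'   \item{counting}{per-schedule counting benchmark: for each repetition
#'     count r the theoretical interval \code{i_t}, integer interval
#'     \code{i}, extraction error \code{e}, the ripe counts of eight
#'     inspection videos (\code{v1_1..v4_2}) and the published mean
#'     relative counting error \code{avg_err_c}.}
#'   \item{counting_gt}{detection-level ground-truth ripe counts of the
#'     eight videos.}
#' }
#' The platform speed underlying \code{counting} was 0.3 m/s.
#'
#' @return Named list of data.frames (and a named numeric vector for
#'   \code{counting_gt}).
#' @export
make_fixture_tables <- function() {
  trial <- function(tag, values)
    data.frame(tag_id = tag, trial = seq_along(values), err = values)
  pos_d <- rbind(trial(8, c(9.6, 10.5, 8.5, 7.2, 6.9)),
                 trial(12, c(17.2, 16.8, 12.6, 12.5, 14.0)),
                 trial(21, c(13.1, 16.6, 17.1, 16.6, 6.6)))
  names(pos_d)[3] <- "err_d"
  pos_x <- rbind(trial(8, c(-9.1, -10.4, -8.3, -5.9, -5.1)),
                 trial(12, c(-16.5, -14.4, -10.1, -11.1, -11.5)),
                 trial(21, c(-8.6, -15.2, -16.2, -11.7, 5.2)))
  names(pos_x)[3] <- "err_x"
  pos_y <- rbind(trial(8, c(-3.2, -0.8, -2.0, -4.1, -4.6)),
                 trial(12, c(-4.7, -8.7, -7.6, -5.8, -8.0)),
                 trial(21, c(-9.9, -6.7, -5.4, -11.8, -4.0)))
  names(pos_y)[3] <- "err_y"

  counting <- data.frame(
    r = c(15, 10, 6, 5, 3, 14, 8, 2, 11, 13, 7, 9, 4, 12),
    i_t = c(2.029, 3.044, 5.073, 6.088, 10.146, 2.174, 3.805, 15.219,
            2.767, 2.341, 4.348, 3.382, 7.610, 2.537),
    i = c(2, 3, 5, 6, 10, 2, 4, 15, 3, 2, 4, 3, 8, 3),
    e = c(0.029, 0.044, 0.073, 0.088, 0.146, 0.174, 0.195, 0.219,
          0.233, 0.341, 0.348, 0.382, 0.390, 0.4635),
    v1_1 = c(28, 28, 29, 28, 30, 30, 27, 28, 25, 33, 31, 31, 27, 23),
    v1_2 = c(29, 29, 29, 29, 26, 31, 27, 29, 26, 33, 31, 32, 27, 24),
    v2_1 = c(31, 31, 30, 31, 29, 33, 30, 31, 28, 36, 34, 34, 30, 26),
    v2_2 = c(31, 31, 31, 31, 30, 34, 30, 29, 28, 36, 34, 34, 30, 26),
    v3_1 = c(43, 43, 43, 43, 44, 46, 41, 44, 39, 50, 46, 48, 41, 36),
    v3_2 = c(46, 46, 46, 47, 46, 49, 42, 49, 42, 53, 48, 51, 42, 38),
    v4_1 = c(37, 37, 37, 37, 36, 40, 35, 36, 34, 43, 40, 41, 35, 31),
    v4_2 = c(36, 36, 35, 35, 35, 38, 34, 33, 32, 41, 39, 40, 34, 30),
    avg_err_c = c(0.032, 0.032, 0.035, 0.038, 0.052, 0.049, 0.072, 0.059,
                  0.116, 0.133, 0.058, 0.083, 0.072, 0.185))

  counting_gt <- c(v1_1 = 30, v1_2 = 30, v2_1 = 32, v2_2 = 32,
                   v3_1 = 44, v3_2 = 44, v4_1 = 37, v4_2 = 37)

  list(positioning_d = pos_d, positioning_x = pos_x, positioning_y = pos_y,
       counting = counting, counting_gt = counting_gt)
}

#' Mean relative counting error of a benchmark schedule row
#'
#' For one row of the \code{counting} fixture, the mean of
#' \code{\link{err_c}} over the eight videos against the ground-truth
#' counts.
#'
#' @param counting the \code{counting} fixture data.frame.
#' @param gt the \code{counting_gt} vector.
#' @param r repetition count selecting the row.
#' @return Mean relative counting error (dimensionless).
#' @export
fixture_mean_err_c <- function(counting, gt, r) {
  row <- counting[counting$r == r, , drop = FALSE]
  if (nrow(row) != 1) stop(sprintf("no benchmark row for r = %d", r), call. = FALSE)
  counts <- as.numeric(row[1, names(gt)])
  mean(err_c(counts, as.numeric(gt)))
}

#' Write the benchmark tables as delimited files
#'
#' Materialises \code{\link{make_fixture_tables}} as tab-separated files
#' (one per table) under \code{dir}; readable back with
#' \code{\link[utils]{read.delim}}.
#'
#' @param dir output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture_tables <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- make_fixture_tables()
  for (nm in c("positioning_d", "positioning_x", "positioning_y", "counting")) {
    utils::write.table(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gt <- data.frame(video = names(tabs$counting_gt),
                   n_gt = as.numeric(tabs$counting_gt))
  utils::write.table(gt, file.path(dir, "counting_gt.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
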