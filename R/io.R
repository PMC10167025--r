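# Plain-text on-disk formats. All numeric fields are written with %.17g so
# doubles round-trip exactly; units are meters / radians / seconds / pixels,
# matching the in-memory objects.

num <- function(x) sprintf("%.17g", x)

io_stop <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' Read / write a tag map
#'
#' One record per tag: id, x, y, theta, comma-separated neighbor ids ("-"
#' for none) and a virtual flag. Readers and writers are mutually inverse
#' on valid data; malformed records are reported with their line number
#' and duplicate ids are rejected by name.
#'
#' @param path file path.
#' @return \code{read_tag_map} returns a \code{\link{tag_map}};
#'   \code{write_tag_map} returns \code{path} invisibly.
#' @export
read_tag_map <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  rows <- list(); edges_from <- integer(); edges_to <- integer()
  seen <- integer()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    f <- strsplit(s, "\t", fixed = TRUE)[[1]]
    if (length(f) != 6)
      io_stop(path, ln, sprintf("expected 6 tab-separated fields, got %d", length(f)))
    id <- suppressWarnings(as.integer(f[1]))
    xyz <- suppressWarnings(as.numeric(f[2:4]))
    if (is.na(id) || any(is.na(xyz)))
      io_stop(path, ln, "malformed numeric field")
    if (id %in% seen)
      io_stop(path, ln, sprintf("duplicate tag id %d", id))
    seen <- c(seen, id)
    if (f[5] != "-") {
      nb <- suppressWarnings(as.integer(strsplit(f[5], ",", fixed = TRUE)[[1]]))
      if (any(is.na(nb))) io_stop(path, ln, "malformed neighbor list")
      edges_from <- c(edges_from, rep(id, length(nb)))
      edges_to <- c(edges_to, nb)
    }
    virt <- f[6]
    if (!virt %in% c("0", "1")) io_stop(path, ln, "virtual flag must be 0 or 1")
    rows[[length(rows) + 1]] <-
      data.frame(id = id, x = xyz[1], y = xyz[2], theta = xyz[3],
                 virtual = virt == "1")
  }
  tags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), x = numeric(), y = numeric(),
               theta = numeric(), virtual = logical())
  tag_map(tags, data.frame(from = edges_from, to = edges_to))
}

#' @rdname read_tag_map
#' @param map a \code{\link{tag_map}}.
#' @export
write_tag_map <- function(map, path) {
  stopifnot(inherits(map, "tag_map"))
  lines <- c("# strawbot tag_map v1",
             "# id\tx\ty\ttheta\tneighbors\tvirtual")
  for (i in seq_len(nrow(map$tags))) {
    id <- map$tags$id[i]
    nb <- tag_neighbors(map, id)
    lines <- c(lines, paste(
      id, num(map$tags$x[i]), num(map$tags$y[i]), num(map$tags$theta[i]),
      if (length(nb)) paste(nb, collapse = ",") else "-",
      as.integer(map$tags$virtual[i]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a detection stream
#'
#' A key-value header block (camera intrinsics, frame count, platform
#' speed) followed by one tab-separated record per detection:
#' frame, label, confidence, xmin, ymin, xmax, ymax. Out-of-bounds or
#' degenerate boxes are rejected with the offending frame index.
#'
#' @param path file path.
#' @return \code{read_detection_stream} returns a
#'   \code{\link{detection_stream}}; the writer returns \code{path}
#'   invisibly.
#' @export
read_detection_stream <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  rows <- vector("list", length(lines)); nr <- 0
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "") next
    if (startsWith(s, "#!")) {
      kv <- strsplit(sub("^#!\\s*", "", s), "\\s+")[[1]]
      if (length(kv) != 2) io_stop(path, ln, "malformed header line")
      hdr[[kv[1]]] <- suppressWarnings(as.numeric(kv[2]))
      next
    }
    if (startsWith(s, "#")) next
    f <- strsplit(s, "\t", fixed = TRUE)[[1]]
    if (length(f) != 7)
      io_stop(path, ln, sprintf("expected 7 fields, got %d", length(f)))
    vals <- suppressWarnings(as.numeric(f[c(1, 3:7)]))
    if (any(is.na(vals))) io_stop(path, ln, "malformed numeric field")
    nr <- nr + 1
    rows[[nr]] <- data.frame(frame = as.integer(vals[1]), label = f[2],
                             confidence = vals[2], xmin = vals[3],
                             ymin = vals[4], xmax = vals[5], ymax = vals[6])
  }
  need <- c("fx", "fy", "cx", "cy", "width", "height", "fps", "speed", "n_frames")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop(sprintf("%s: missing header keys: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  cam <- camera_model(fx = hdr$fx, fy = hdr$fy, cx = hdr$cx, cy = hdr$cy,
                      width = hdr$width, height = hdr$height, fps = hdr$fps)
  det <- if (nr) do.call(rbind, rows[seq_len(nr)]) else empty_detections()
  detection_stream(cam, hdr$speed, det, n_frames = hdr$n_frames)
}

#' @rdname read_detection_stream
#' @param stream a \code{\link{detection_stream}}.
#' @export
write_detection_stream <- function(stream, path) {
  stopifnot(inherits(stream, "detection_stream"))
  cam <- stream$camera
  hdr <- c("# strawbot detection_stream v1",
           sprintf("#! fx %s", num(cam$fx)), sprintf("#! fy %s", num(cam$fy)),
           sprintf("#! cx %s", num(cam$cx)), sprintf("#! cy %s", num(cam$cy)),
           sprintf("#! width %d", as.integer(cam$width)),
           sprintf("#! height %d", as.integer(cam$height)),
           sprintf("#! fps %s", num(cam$fps)),
           sprintf("#! speed %s", num(stream$speed)),
           sprintf("#! n_frames %d", stream$n_frames),
           "# frame\tlabel\tconfidence\txmin\tymin\txmax\tymax")
  d <- stream$detections
  body <- if (nrow(d)) paste(d$frame, d$label, num(d$confidence), num(d$xmin),
                             num(d$ymin), num(d$xmax), num(d$ymax), sep = "\t")
          else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a sensor log
#'
#' Two sections: \code{[samples]} with columns t, dsl, dsr, dtheta and
#' \code{[observations]} with columns t, id, rel_x, rel_y, rel_theta.
#'
#' @param path file path.
#' @return \code{read_sensor_log} returns a \code{\link{sensor_log}};
#'   the writer returns \code{path} invisibly.
#' @export
read_sensor_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  section <- ""
  smp <- list(); obs <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "" || startsWith(s, "#")) next
    if (s %in% c("[samples]", "[observations]")) { section <- s; next }
    f <- suppressWarnings(as.numeric(strsplit(s, "\t", fixed = TRUE)[[1]]))
    if (any(is.na(f))) io_stop(path, ln, "malformed numeric field")
    if (section == "[samples]") {
      if (length(f) != 4) io_stop(path, ln, "expected 4 fields in [samples]")
      smp[[length(smp) + 1]] <- f
    } else if (section == "[observations]") {
      if (length(f) != 5) io_stop(path, ln, "expected 5 fields in [observations]")
      obs[[length(obs) + 1]] <- f
    } else io_stop(path, ln, "record before any section header")
  }
  samples <- if (length(smp)) {
    m <- do.call(rbind, smp)
    data.frame(t = m[, 1], dsl = m[, 2], dsr = m[, 3], dtheta = m[, 4])
  } else data.frame(t = numeric(), dsl = numeric(), dsr = numeric(),
                    dtheta = numeric())
  observations <- if (length(obs)) {
    m <- do.call(rbind, obs)
    data.frame(t = m[, 1], id = as.integer(m[, 2]), rel_x = m[, 3],
               rel_y = m[, 4], rel_theta = m[, 5])
  } else data.frame(t = numeric(), id = integer(), rel_x = numeric(),
                    rel_y = numeric(), rel_theta = numeric())
  sensor_log(samples, observations)
}

#' @rdname read_sensor_log
#' @param log a \code{\link{sensor_log}}.
#' @export
write_sensor_log <- function(log, path) {
  stopifnot(inherits(log, "sensor_log"))
  s <- log$samples; o <- log$observations
  lines <- c("# strawbot sensor_log v1", "[samples]",
             if (nrow(s)) paste(num(s$t), num(s$dsl), num(s$dsr),
                                num(s$dtheta), sep = "\t"),
             "[observations]",
             if (nrow(o)) paste(num(o$t), o$id, num(o$rel_x), num(o$rel_y),
                                num(o$rel_theta), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
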