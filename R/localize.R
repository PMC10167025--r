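# Two-case localization and graph path planning on the tag map.

#' Localize the robot on a tag map
#'
#' Two cases. With a current tag observation, the robot pose is the tag's
#' map pose composed with the inverse of the observed tag-in-robot pose
#' (direct global fix). Without one, the pose is the last fix propagated
#' by the odometry accumulated since that fix.
#'
#' @param map a \code{\link{tag_map}} (non-empty).
#' @param observation \code{NULL}, or a list with \code{id} and
#'   \code{rel_pose} (tag pose in the robot frame, \code{\link{pose2d}}).
#' @param last_fix \code{NULL}, or a list with \code{pose} (robot pose at
#'   the fix) and \code{odom} (dead-reckoned pose at the fix). Required
#'   when \code{observation} is \code{NULL}.
#' @param odom_now current dead-reckoned pose (same chain as
#'   \code{last_fix$odom}).
#' @return The robot's global \code{\link{pose2d}}.
#' @export
localize <- function(map, observation = NULL, last_fix = NULL, odom_now = NULL) {
  stopifnot(inherits(map, "tag_map"))
  if (nrow(map$tags) == 0) stop("empty tag map", call. = FALSE)
  if (!is.null(observation)) {
    if (!observation$id %in% map$tags$id)
      stop(sprintf("observed tag %d is not in the map", observation$id),
           call. = FALSE)
    return(pose_compose(tag_pose(map, observation$id),
                        pose_inverse(observation$rel_pose)))
  }
  if (is.null(last_fix) || is.null(odom_now))
    stop("no tag observation and no previous fix: cannot localize", call. = FALSE)
  pose_compose(last_fix$pose, pose_between(last_fix$odom, odom_now))
}

#' Shortest tag path by breadth-first search
#'
#' Fewest-hop path on the undirected tag adjacency. A free-position goal
#' (length-2 numeric \code{c(x, y)}) first inserts a virtual tag splitting
#' the nearest map edge; the returned path then ends at the virtual tag
#' (its id, pose and neighbor pair are attached as attributes). The input
#' map is never modified.
#'
#' @param map a \code{\link{tag_map}}.
#' @param start_id starting tag id.
#' @param goal goal tag id (scalar) or free position \code{c(x, y)} in
#'   meters.
#' @return Integer vector of tag ids from start to goal. For a free goal,
#'   attributes \code{virtual_id}, \code{virtual_pose},
#'   \code{virtual_neighbors} describe the inserted tag.
#' @export
plan_path <- function(map, start_id, goal) {
  stopifnot(inherits(map, "tag_map"))
  if (!start_id %in% map$tags$id)
    stop(sprintf("start tag %d is not in the map", start_id), call. = FALSE)
  virtual <- NULL
  if (length(goal) == 2 && is.numeric(goal) && !goal[1] %in% map$tags$id) {
    ins <- insert_virtual_tag(map, goal)
    map <- ins$map; virtual <- ins
    goal_id <- ins$id
  } else {
    goal_id <- goal
    if (!goal_id %in% map$tags$id)
      stop(sprintf("goal tag %d is not in the map", goal_id), call. = FALSE)
  }
  if (nrow(map$edges) == 0 && start_id != goal_id)
    stop("tag map has no edges; goal unreachable", call. = FALSE)
  g <- igraph::graph_from_data_frame(
    map$edges, directed = FALSE,
    vertices = data.frame(name = map$tags$id))
  sp <- suppressWarnings(igraph::shortest_paths(
    g, from = as.character(start_id), to = as.character(goal_id)))
  ids <- as.integer(names(sp$vpath[[1]]))
  if (length(ids) == 0 && start_id != goal_id)
    stop(sprintf("tag %s is unreachable from tag %d",
                 paste(goal_id, collapse = ","), start_id), call. = FALSE)
  if (!is.null(virtual)) {
    attr(ids, "virtual_id") <- virtual$id
    attr(ids, "virtual_pose") <- virtual$pose
    attr(ids, "virtual_neighbors") <- virtual$neighbors
  }
  ids
}

# Split the map edge nearest to point (x, y) with a temporary tag.
insert_virtual_tag <- function(map, point) {
  if (nrow(map$edges) == 0)
    stop("cannot insert a virtual tag into a map without edges", call. = FALSE)
  best <- NULL; best_d <- Inf
  for (k in seq_len(nrow(map$edges))) {
    a <- tag_pose(map, map$edges$from[k]); b <- tag_pose(map, map$edges$to[k])
    ab <- c(b[["x"]] - a[["x"]], b[["y"]] - a[["y"]])
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) 0 else
      max(0, min(1, sum((point - c(a[["x"]], a[["y"]])) * ab) / len2))
    proj <- c(a[["x"]], a[["y"]]) + tt * ab
    d2 <- sum((point - proj)^2)
    if (d2 < best_d) {
      best_d <- d2
      best <- list(k = k, proj = proj, heading = atan2(ab[2], ab[1]))
    }
  }
  vid <- max(map$tags$id) + 1L
  from <- map$edges$from[best$k]; to <- map$edges$to[best$k]
  tags <- rbind(map$tags,
                data.frame(id = vid, x = best$proj[1], y = best$proj[2],
                           theta = best$heading, virtual = TRUE))
  edges <- rbind(map$edges[-best$k, , drop = FALSE],
                 data.frame(from = c(from, vid), to = c(vid, to)))
  list(map = tag_map(tags, edges), id = vid,
       pose = pose2d(best$proj[1], best$proj[2], best$heading),
       neighbors = sort(c(from, to)))
}

#' Local path target
#'
#' The controller steers towards the tag two ahead of the last tag passed
#' (keeping the commanded direction stable on a straight run), clamped at
#' the final path tag so the target never moves beyond the goal.
#'
#' @param path integer vector of tag ids (non-empty).
#' @param last_passed_index 1-based index into \code{path} of the last
#'   tag passed (0 if none passed yet).
#' @return The target tag id, \code{path[min(last_passed_index + 2,
#'   length(path))]}.
#' @export
local_target <- function(path, last_passed_index) {
  if (length(path) == 0) stop("empty path", call. = FALSE)
  path[[min(max(last_passed_index, 0) + 2, length(path))]]
}
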