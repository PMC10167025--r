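# Pose-graph mapping of ground fiducials with loop-closure optimisation.
#
# Vertices are the global planar poses of the tags; each edge carries the
# odometry-composed relative pose between two consecutively sighted tags,
# weighted by a (diagonal) information matrix. The map is the minimiser of
#   0.5 * sum_ij  e_ij' Omega_ij e_ij
# with e_ij = [R_i'(p_j - p_i) - p_hat_ij ; theta_j - theta_i - theta_hat_ij],
# solved by Levenberg-Marquardt with the first-sighted tag anchored.

#' Pose-graph edge residual
#'
#' Mismatch between the relative pose predicted by two vertex states and
#' the measured relative pose: the translational part is expressed in
#' vertex i's frame, the angular part is a wrapped difference.
#'
#' @param x_i,x_j vertex poses (\code{\link{pose2d}}).
#' @param p_hat measured relative translation, length-2 (meters).
#' @param theta_hat measured relative rotation, radians.
#' @return Numeric length-3 residual (ex, ey, etheta).
#' @export
pgo_residual <- function(x_i, x_j, p_hat, theta_hat) {
  x_i <- as_pose2d(x_i); x_j <- as_pose2d(x_j)
  ci <- cos(x_i[["theta"]]); si <- sin(x_i[["theta"]])
  dx <- x_j[["x"]] - x_i[["x"]]; dy <- x_j[["y"]] - x_i[["y"]]
  c(ci * dx + si * dy - p_hat[1],
    -si * dx + ci * dy - p_hat[2],
    wrap_angle(x_j[["theta"]] - x_i[["theta"]] - theta_hat))
}

new_pose_graph <- function(vertices, edges, anchor) {
  stopifnot(all(c("id", "x", "y", "theta") %in% names(vertices)),
            all(c("from", "to", "dx", "dy", "dtheta", "wx", "wy", "wt") %in% names(edges)))
  if (anyDuplicated(vertices$id)) stop("duplicate vertex id", call. = FALSE)
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$from, edges$to)), vertices$id)
    if (length(unknown))
      stop(sprintf("edge references missing vertex %d", unknown[1]), call. = FALSE)
    if (any(edges$wx < 0 | edges$wy < 0 | edges$wt < 0))
      stop("information weights must be >= 0", call. = FALSE)
  }
  if (!anchor %in% vertices$id) stop("anchor vertex not in graph", call. = FALSE)
  structure(list(vertices = vertices, edges = edges, anchor = anchor),
            class = "pose_graph")
}

#' @export
print.pose_graph <- function(x, ...) {
  cat(sprintf("<pose_graph> %d vertices, %d edges, anchor = tag %d, objective = %.6g\n",
              nrow(x$vertices), nrow(x$edges), x$anchor, graph_objective(x)))
  invisible(x)
}

#' Weighted least-squares objective of a pose graph
#'
#' \code{0.5 * sum(e' Omega e)} over all edges at the graph's current
#' vertex poses.
#'
#' @param graph a \code{pose_graph}.
#' @return Scalar objective value.
#' @export
graph_objective <- function(graph) {
  stopifnot(inherits(graph, "pose_graph"))
  r <- graph_residuals(graph)
  0.5 * sum(r$w * r$e^2)
}

# stacked residuals and weights; rows of v looked up once for speed
graph_residuals <- function(graph) {
  v <- graph$vertices; ed <- graph$edges
  ii <- match(ed$from, v$id); jj <- match(ed$to, v$id)
  ci <- cos(v$theta[ii]); si <- sin(v$theta[ii])
  dx <- v$x[jj] - v$x[ii]; dy <- v$y[jj] - v$y[ii]
  ex <- ci * dx + si * dy - ed$dx
  ey <- -si * dx + ci * dy - ed$dy
  et <- wrap_angle(v$theta[jj] - v$theta[ii] - ed$dtheta)
  list(e = as.vector(rbind(ex, ey, et)),
       w = as.vector(rbind(ed$wx, ed$wy, ed$wt)),
       ii = ii, jj = jj)
}

#' Build a pose graph from a sensor log
#'
#' Dead-reckons the robot trajectory, turns each tag-sighting event into a
#' tag-pose estimate (odometric pose composed with the observed
#' tag-in-robot pose) and links consecutively sighted tags with the
#' resulting relative pose. Consecutive raw observations of the same tag
#' are collapsed into one sighting (the observation with the smallest
#' range, i.e. closest to directly above the tag). Re-sighted tags keep
#' their original vertex, so out-and-back routes produce loop-closure
#' edges. The first-sighted tag becomes the anchor.
#'
#' @param log a \code{\link{sensor_log}} with at least two observations.
#' @param omega length-3 information weights (x, y, theta) applied to
#'   every edge.
#' @param start dead-reckoning start pose.
#' @return A \code{pose_graph}.
#' @export
build_pose_graph <- function(log, omega = c(1, 1, 0.5), start = pose2d()) {
  stopifnot(inherits(log, "sensor_log"), length(omega) == 3)
  obs <- log$observations
  if (nrow(obs) < 2)
    stop("need at least two tag observations to build a pose graph", call. = FALSE)
  traj <- integrate_odometry(log, start)
  s_t <- log$samples$t

  # sighting events: collapse consecutive runs of the same id
  runs <- rle(obs$id)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  ev_rows <- integer(length(runs$values))
  for (k in seq_along(runs$values)) {
    idx <- starts[k]:ends[k]
    rng <- sqrt(obs$rel_x[idx]^2 + obs$rel_y[idx]^2)
    ev_rows[k] <- idx[which.min(rng)]
  }
  if (length(ev_rows) < 2)
    stop("need at least two tag sightings to build a pose graph", call. = FALSE)

  ev <- obs[ev_rows, , drop = FALSE]
  tag_est <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    dr_idx <- sum(s_t <= ev$t[k]) + 1L
    dr <- pose2d(traj$x[dr_idx], traj$y[dr_idx], traj$theta[dr_idx])
    tag_est[[k]] <- pose_compose(dr, pose2d(ev$rel_x[k], ev$rel_y[k], ev$rel_theta[k]))
  }

  first <- !duplicated(ev$id)
  vertices <- data.frame(
    id = ev$id[first],
    x = vapply(tag_est[first], `[[`, numeric(1), "x"),
    y = vapply(tag_est[first], `[[`, numeric(1), "y"),
    theta = vapply(tag_est[first], `[[`, numeric(1), "theta"))

  ne <- nrow(ev) - 1L
  edges <- data.frame(from = ev$id[-nrow(ev)], to = ev$id[-1L],
                      dx = numeric(ne), dy = numeric(ne), dtheta = numeric(ne),
                      wx = omega[1], wy = omega[2], wt = omega[3])
  for (k in seq_len(ne)) {
    z <- pose_between(tag_est[[k]], tag_est[[k + 1]])
    edges$dx[k] <- z[["x"]]; edges$dy[k] <- z[["y"]]; edges$dtheta[k] <- z[["theta"]]
  }
  edges <- edges[edges$from != edges$to, , drop = FALSE]  # degenerate re-sighting
  rownames(edges) <- NULL
  new_pose_graph(vertices, edges, anchor = ev$id[1])
}

#' Optimise a pose graph into a tag map
#'
#' Levenberg-Marquardt minimisation of the weighted squared residuals over
#' all vertex poses, the anchor held fixed (gauge). Damping starts at
#' \code{lambda0} and adapts by factors of 10; iteration stops when the
#' gradient max-norm falls below \code{grad_tol} or after \code{max_iter}
#' iterations. Accepted steps never increase the objective.
#'
#' @param graph a \code{pose_graph} (connected, anchor set).
#' @param lambda0 initial damping.
#' @param grad_tol gradient max-norm stopping tolerance.
#' @param max_iter iteration cap.
#' @return A \code{\link{tag_map}} whose adjacency is the distinct tag
#'   pairs linked by graph edges; attribute \code{"optimization"} carries
#'   a list (objective_initial, objective, iterations, grad_norm,
#'   converged). Warns on non-convergence with the final gradient norm.
#' @export
optimize_graph <- function(graph, lambda0 = 1e-3, grad_tol = 1e-8,
                           max_iter = 200L) {
  stopifnot(inherits(graph, "pose_graph"))
  v <- graph$vertices; ed <- graph$edges
  if (nrow(ed) == 0) stop("pose graph has no edges", call. = FALSE)
  g_conn <- igraph::graph_from_data_frame(
    ed[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = v$id))
  if (igraph::components(g_conn)$no != 1L)
    stop("pose graph is disconnected; cannot optimize", call. = FALSE)

  n <- nrow(v)
  free <- which(v$id != graph$anchor)
  # parameter layout: (x, y, theta) per free vertex
  col_of <- integer(n); col_of[free] <- seq_along(free)
  state <- cbind(v$x, v$y, v$theta)

  residual_jacobian <- function(state) {
    ii <- match(ed$from, v$id); jj <- match(ed$to, v$id)
    ci <- cos(state[ii, 3]); si <- sin(state[ii, 3])
    dx <- state[jj, 1] - state[ii, 1]; dy <- state[jj, 2] - state[ii, 2]
    ex <- ci * dx + si * dy - ed$dx
    ey <- -si * dx + ci * dy - ed$dy
    et <- wrap_angle(state[jj, 3] - state[ii, 3] - ed$dtheta)
    m <- nrow(ed)
    e <- as.vector(rbind(ex, ey, et))
    w <- as.vector(rbind(ed$wx, ed$wy, ed$wt))
    J <- matrix(0, 3 * m, 3 * length(free))
    for (k in seq_len(m)) {
      rows <- (3 * k - 3) + 1:3
      Rt <- matrix(c(ci[k], -si[k], si[k], ci[k]), 2, 2)  # R_i^T
      dRt <- matrix(c(-si[k], -ci[k], ci[k], -si[k]), 2, 2)
      if (col_of[ii[k]] > 0) {
        cols <- (3 * col_of[ii[k]] - 3) + 1:3
        J[rows[1:2], cols[1:2]] <- -Rt
        J[rows[1:2], cols[3]] <- dRt %*% c(dx[k], dy[k])
        J[rows[3], cols[3]] <- -1
      }
      if (col_of[jj[k]] > 0) {
        cols <- (3 * col_of[jj[k]] - 3) + 1:3
        J[rows[1:2], cols[1:2]] <- Rt
        J[rows[3], cols[3]] <- 1
      }
    }
    list(e = e, w = w, J = J)
  }

  cost_of <- function(rj) 0.5 * sum(rj$w * rj$e^2)
  rj <- residual_jacobian(state)
  cost <- cost_of(rj)
  cost0 <- cost
  lambda <- lambda0
  iter <- 0L; gnorm <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    WJ <- rj$J * rj$w
    H <- crossprod(rj$J, WJ)
    g <- crossprod(WJ, rj$e)
    gnorm <- max(abs(g))
    if (gnorm < grad_tol) { iter <- iter - 1L; break }
    stepped <- FALSE
    while (lambda <= 1e12) {
      D <- diag(pmax(diag(H), 1e-12), nrow(H))
      delta <- tryCatch(solve(H + lambda * D, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- state
        for (f in seq_along(free)) {
          vi <- free[f]
          cand[vi, 1] <- state[vi, 1] + delta[3 * f - 2]
          cand[vi, 2] <- state[vi, 2] + delta[3 * f - 1]
          cand[vi, 3] <- wrap_angle(state[vi, 3] + delta[3 * f])
        }
        rj_cand <- residual_jacobian(cand)
        if (cost_of(rj_cand) < cost) {
          state <- cand; rj <- rj_cand; cost <- cost_of(rj_cand)
          lambda <- max(lambda / 10, 1e-12)
          stepped <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!stepped) break
  }
  WJ <- rj$J * rj$w
  gnorm <- max(abs(crossprod(WJ, rj$e)))
  converged <- gnorm < grad_tol
  if (!converged)
    warning(sprintf("pose-graph optimisation stopped without convergence (gradient max-norm %.3g)",
                    gnorm))

  tags <- data.frame(id = v$id, x = state[, 1], y = state[, 2],
                     theta = wrap_angle(state[, 3]),
                     virtual = FALSE)
  map <- tag_map(tags, data.frame(from = ed$from, to = ed$to))
  attr(map, "optimization") <- list(objective_initial = cost0,
                                    objective = cost, iterations = iter,
                                    grad_norm = gnorm, converged = converged)
  map
}
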