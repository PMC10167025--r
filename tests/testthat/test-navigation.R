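test_that("dead reckoning advances along the pre-update heading", {
  expect_equal(dead_reckon_step(pose2d(), 0, 0.5, 0.5), pose2d(0.5, 0, 0))
  # pure spin: position fixed, heading advances by the IMU increment
  p <- dead_reckon_step(pose2d(1, 2, 0.4), 0.2, -0.1, 0.1)
  expect_equal(as.numeric(p), c(1, 2, 0.6))
  # heading pi/2 before the step: motion goes +y, the new heading applies later
  p2 <- dead_reckon_step(pose2d(0, 0, pi / 2), 0.1, 0.5, 0.5)
  expect_equal(as.numeric(p2), c(0, 0.5, pi / 2 + 0.1), tolerance = 1e-12)
})

test_that("integrated odometry closes a square loop", {
  leg <- data.frame(t = 0, dsl = rep(0.25, 4), dsr = rep(0.25, 4), dtheta = 0)
  spin <- data.frame(t = 0, dsl = -0.1, dsr = 0.1, dtheta = pi / 2)
  s <- do.call(rbind, rep(list(rbind(leg, spin)), 4))
  s$t <- seq_len(nrow(s)) * 0.1
  traj <- integrate_odometry(sensor_log(s))
  expect_equal(nrow(traj), nrow(s) + 1)
  end <- traj[nrow(traj), ]
  expect_equal(c(end$x, end$y), c(0, 0), tolerance = 1e-9)
  # forward path length equals the summed mean wheel displacement
  expect_equal(sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2)),
               sum((s$dsl + s$dsr) / 2), tolerance = 1e-9)
  expect_equal(nrow(integrate_odometry(sensor_log())), 1)
})

test_that("pose-graph residual vanishes iff the measurement matches", {
  expect_equal(pgo_residual(pose2d(0, 0, 0), pose2d(1, 0, 0), c(1, 0), 0),
               c(0, 0, 0))
  # translational part is expressed in vertex i's rotated frame
  expect_equal(pgo_residual(pose2d(0, 0, pi / 2), pose2d(0, 1, pi / 2), c(1, 0), 0),
               c(0, 0, 0), tolerance = 1e-12)
  set.seed(11)
  for (k in 1:10) {
    xi <- pose2d(runif(1, -2, 2), runif(1, -2, 2), runif(1, -pi, pi))
    xj <- pose2d(runif(1, -2, 2), runif(1, -2, 2), runif(1, -pi, pi))
    z <- pose_between(xi, xj)
    expect_equal(pgo_residual(xi, xj, c(z[["x"]], z[["y"]]), z[["theta"]]),
                 c(0, 0, 0), tolerance = 1e-12)
    off <- pgo_residual(xi, xj, c(z[["x"]] + 0.1, z[["y"]]), z[["theta"]])
    expect_gt(sum(abs(off)), 0.09)
  }
})

test_that("graph construction: vertices per distinct tag, edges per sighting pair", {
  map <- make_tag_layout(6, 1.3, "line")
  drv <- simulate_drive(map, c(0:5, 4:0), noise = noiseless(), seed = 1)
  g <- build_pose_graph(drv$log)
  expect_equal(nrow(g$vertices), 6)        # revisits reuse vertices
  expect_equal(nrow(g$edges), 10)          # 11 sighting events -> 10 edges
  expect_equal(g$anchor, 0)
  # loop closures: more edges than a spanning tree needs
  expect_gt(nrow(g$edges), nrow(g$vertices) - 1)
  # noiseless log: zero residuals at initialization
  expect_lt(graph_objective(g), 1e-16)
  two <- simulate_drive(map, 0:1, noise = noiseless(), seed = 1)
  g2 <- build_pose_graph(two$log)
  expect_equal(nrow(g2$vertices), 2)
  expect_equal(nrow(g2$edges), 1)
  expect_error(build_pose_graph(sensor_log()), "two tag observations")
})

test_that("optimisation recovers a noiseless loop and never raises the objective", {
  map <- make_tag_layout(12, 1.3, "loop")
  drv <- simulate_drive(map, c(0:11, 0), noise = noiseless(), seed = 2)
  g <- build_pose_graph(drv$log)
  m <- optimize_graph(g)
  info <- attr(m, "optimization")
  expect_true(info$converged)
  expect_lte(info$objective, info$objective_initial)
  expect_lt(info$grad_norm, 1e-8)
  expect_lt(max(tag_position_errors(m, map)), 1e-6)
  th_err <- abs(wrap_angle(m$tags$theta - map$tags$theta[match(m$tags$id, map$tags$id)]))
  expect_lt(max(th_err), 1e-8)
  # a graph already at its optimum is returned unchanged
  g_opt <- g
  g_opt$vertices <- m$tags[, c("id", "x", "y", "theta")]
  m2 <- optimize_graph(g_opt)
  expect_lt(max(tag_position_errors(m2, m)), 1e-9)
})

test_that("LM solution matches a general-purpose optimiser on a small graph", {
  map <- make_tag_layout(5, 1.3, "line")
  drv <- simulate_drive(map, 0:4, noise = noise_model(), seed = 5)
  g <- build_pose_graph(drv$log)
  m <- optimize_graph(g)

  # independent oracle: BFGS on the hand-coded weighted objective,
  # anchor excluded from the parameter vector
  v <- g$vertices; ed <- g$edges
  free <- which(v$id != g$anchor)
  obj <- function(par) {
    st <- cbind(v$x, v$y, v$theta)
    st[free, ] <- matrix(par, ncol = 3, byrow = TRUE)
    tot <- 0
    for (k in seq_len(nrow(ed))) {
      i <- match(ed$from[k], v$id); j <- match(ed$to[k], v$id)
      ci <- cos(st[i, 3]); si <- sin(st[i, 3])
      dx <- st[j, 1] - st[i, 1]; dy <- st[j, 2] - st[i, 2]
      e <- c(ci * dx + si * dy - ed$dx[k],
             -si * dx + ci * dy - ed$dy[k],
             wrap_angle(st[j, 3] - st[i, 3] - ed$dtheta[k]))
      tot <- tot + 0.5 * sum(c(ed$wx[k], ed$wy[k], ed$wt[k]) * e^2)
    }
    tot
  }
  par0 <- as.vector(t(cbind(v$x, v$y, v$theta)[free, ]))
  ref <- stats::optim(par0, obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  info <- attr(m, "optimization")
  expect_equal(info$objective, ref$value, tolerance = 1e-6)
  ref_state <- matrix(ref$par, ncol = 3, byrow = TRUE)
  got <- as.matrix(m$tags[match(v$id[free], m$tags$id), c("x", "y", "theta")])
  expect_equal(unname(got), unname(ref_state), tolerance = 1e-4)
})

test_that("optimisation reduces map error on noisy loops (Monte Carlo)", {
  map <- make_tag_layout(12, 1.3, "loop")
  improved <- logical(10)
  for (s in seq_len(10)) {
    drv <- simulate_drive(map, c(0:11, 0), noise = noise_model(), seed = 100 + s)
    g <- build_pose_graph(drv$log)
    init_map <- tag_map(cbind(g$vertices, virtual = FALSE),
                        data.frame(from = integer(), to = integer()))
    m <- suppressWarnings(optimize_graph(g))
    improved[s] <- mean(tag_position_errors(m, map)) <
      mean(tag_position_errors(init_map, map))
  }
  expect_gte(mean(improved), 0.9)
})

test_that("two-case localization: tag fix or odometry propagation", {
  map <- tag_map(data.frame(id = 3, x = 2, y = 0, theta = 0, virtual = FALSE))
  fix <- localize(map, observation = list(id = 3, rel_pose = pose2d(0.5, 0, 0)))
  expect_equal(as.numeric(fix), c(1.5, 0, 0))
  # no new observation, zero odometry delta: the last fix is returned
  odom <- pose2d(7, 7, 0.3)
  same <- localize(map, last_fix = list(pose = fix, odom = odom), odom_now = odom)
  expect_equal(as.numeric(same), as.numeric(fix), tolerance = 1e-12)
  # odometry delta is composed onto the fix
  moved <- localize(map, last_fix = list(pose = fix, odom = pose2d()),
                    odom_now = pose2d(1, 0, 0))
  expect_equal(as.numeric(moved), c(2.5, 0, 0), tolerance = 1e-12)
  expect_error(localize(map, observation = list(id = 9, rel_pose = pose2d())),
               "tag 9")
  expect_error(localize(map), "cannot localize")
})

test_that("BFS path matches the exhaustive fewest-hop oracle", {
  chain <- make_tag_layout(4, 1.3, "line")
  expect_equal(plan_path(chain, 0, 3), 0:3)
  set.seed(21)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    map <- random_connected_map(n, extra_edges = sample(0:3, 1))
    ends <- sample(0:(n - 1), 2)
    path <- plan_path(map, ends[1], ends[2])
    expect_equal(path[1], ends[1])
    expect_equal(path[length(path)], ends[2])
    # consecutive path tags are adjacent on the map
    for (j in seq_len(length(path) - 1))
      expect_true(path[j + 1] %in% tag_neighbors(map, path[j]))
    expect_equal(length(path) - 1,
                 brute_force_hops(map$edges, ends[1], ends[2], n))
  }
  lonely <- tag_map(data.frame(id = 0:2, x = 0:2, y = 0, theta = 0,
                               virtual = FALSE),
                    data.frame(from = 0L, to = 1L))
  expect_error(plan_path(lonely, 0, 2), "unreachable")
})

test_that("free-position goals insert a virtual tag on the nearest edge", {
  map <- make_tag_layout(10, 1.3, "line")
  goal <- c(7.5 * 1.3, 0.2)  # midway between tags 7 and 8, off-axis
  path <- plan_path(map, 0, goal)
  vid <- attr(path, "virtual_id")
  expect_equal(path[length(path)], vid)
  expect_equal(attr(path, "virtual_neighbors"), c(7, 8))
  vp <- attr(path, "virtual_pose")
  expect_equal(vp[["x"]], 7.5 * 1.3, tolerance = 1e-9)
  expect_equal(vp[["y"]], 0)  # projected onto the edge
  # the source map is untouched
  expect_equal(nrow(map$tags), 10)
})

test_that("local target is two tags ahead, clamped at the goal", {
  path <- 5:23
  expect_equal(local_target(path, 1), 7)   # passing tag 5 targets tag 7
  expect_equal(local_target(path, 18), 23) # passing tag 22: target stays 23
  expect_equal(local_target(path, 19), 23)
  expect_equal(local_target(c(4, 9), 0), 9)
})

test_that("control law: saturation, anti-windup, and rest at the goal", {
  gains <- control_gains(v_max = 0.3, omega_max = 1, integral_limit = 0.5)
  at <- control_step(pose2d(1, 1, 0.7), pose2d(1, 1, 0), gains)
  expect_equal(c(at$v, at$omega), c(0, 0))
  # far target dead ahead: v saturates, no turn
  far <- control_step(pose2d(), pose2d(100, 0, 0), gains)
  expect_equal(far$v, gains$v_max)
  expect_equal(far$omega, 0)
  # persistent heading error: integral stays clamped over 1000 steps
  st <- controller_state()
  for (k in 1:1000) {
    out <- control_step(pose2d(0, 0, pi / 2), pose2d(10, 0, 0), gains, st)
    st <- out$state
    expect_lte(abs(st$integral), gains$integral_limit)
    expect_lte(abs(out$omega), gains$omega_max)
  }
})

test_that("differential-drive wheel mapping inverts exactly", {
  expect_equal(wheel_speeds(0.3, 0, 0.4), c(left = 0.3, right = 0.3))
  expect_equal(wheel_speeds(0, 2, 0.4), c(left = -0.4, right = 0.4))
  for (v in c(-0.2, 0, 0.35)) for (w in c(-1.5, 0, 0.7)) {
    ws <- wheel_speeds(v, w, 0.4)
    expect_equal(unname(body_speeds(ws["left"], ws["right"], 0.4)), c(v, w))
  }
})

test_that("closed-loop drive reaches the goal without overshoot", {
  map <- make_tag_layout(10, 1.3, "line")
  path <- plan_path(map, 0, 9)
  res <- drive_to_goal(map, path, control_gains(v_max = 0.3))
  expect_true(res$reached)
  expect_lt(res$overshoot, 0.03)
  expect_lte(max(res$trajectory$v), 0.3 + 1e-12)
})
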