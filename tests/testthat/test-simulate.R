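test_that("tag layouts have the requested count, spacing and adjacency", {
  m45 <- make_tag_layout(45, 1.3, "loop")
  expect_equal(nrow(m45$tags), 45)
  expect_equal(nrow(m45$edges), 45)        # closed route
  # consecutive tags are one spacing apart along the route
  for (k in 1:44) {
    a <- tag_pose(m45, k - 1); b <- tag_pose(m45, k)
    d <- sqrt((a[["x"]] - b[["x"]])^2 + (a[["y"]] - b[["y"]])^2)
    expect_lte(d, 1.3 + 1e-9)
    expect_true(k %in% tag_neighbors(m45, k - 1))
  }
  m2 <- make_tag_layout(2, 0.8, "line")
  expect_equal(nrow(m2$edges), 1)
  a <- tag_pose(m2, 0); b <- tag_pose(m2, 1)
  expect_equal(sqrt(sum((c(a[["x"]], a[["y"]]) - c(b[["x"]], b[["y"]]))^2)), 0.8)
  # total route length of a line equals count-1 spacings
  m <- make_tag_layout(7, 1.1, "line")
  expect_equal(max(m$tags$x), 6 * 1.1)
})

test_that("zero-noise drives invert exactly under dead reckoning", {
  map <- make_tag_layout(8, 1.3, "loop")
  drv <- simulate_drive(map, c(0:7, 0), noise = noiseless(), seed = 1)
  start <- tag_pose(map, 0)
  traj <- integrate_odometry(drv$log, start)
  expect_equal(tail(traj$x, 1), tail(drv$truth$x, 1), tolerance = 1e-9)
  expect_equal(tail(traj$y, 1), tail(drv$truth$y, 1), tolerance = 1e-9)
  # returns to the charging-pile tag
  expect_equal(c(tail(traj$x, 1), tail(traj$y, 1)),
               c(start[["x"]], start[["y"]]), tolerance = 1e-9)
  # zero-noise observations are exact relative poses
  obs <- drv$log$observations
  expect_gt(nrow(obs), 0)
  k <- which.max(obs$t)
  idx <- sum(drv$log$samples$t <= obs$t[k]) + 1
  robot <- pose2d(drv$truth$x[idx], drv$truth$y[idx], drv$truth$theta[idx])
  rel <- pose_between(robot, tag_pose(map, obs$id[k]))
  expect_equal(c(obs$rel_x[k], obs$rel_y[k]),
               c(rel[["x"]], rel[["y"]]), tolerance = 1e-9)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  map <- make_tag_layout(6, 1.3, "line")
  a <- simulate_drive(map, 0:5, noise = noise_model(), seed = 9)
  b <- simulate_drive(map, 0:5, noise = noise_model(), seed = 9)
  expect_identical(a, b)
  setup <- exact_setup()
  fruit <- make_fruit_scene(10, 5, 5, seed = 4)
  s1 <- render_detection_stream(fruit, setup$camera, setup$v, c(0, 11),
                                noise = noise_model(fn_rate = 0.1,
                                                    fp_rate = 0.1,
                                                    bbox_jitter_sd = 1),
                                seed = 13)
  s2 <- render_detection_stream(fruit, setup$camera, setup$v, c(0, 11),
                                noise = noise_model(fn_rate = 0.1,
                                                    fp_rate = 0.1,
                                                    bbox_jitter_sd = 1),
                                seed = 13)
  expect_identical(s1$detections, s2$detections)
})

test_that("dead-reckoning error grows with route length under noise", {
  map <- make_tag_layout(16, 1.3, "line")
  err_at <- function(n_tags) {
    errs <- vapply(1:20, function(s) {
      drv <- simulate_drive(map, 0:(n_tags - 1), noise = noise_model(),
                            seed = 500 + s)
      traj <- integrate_odometry(drv$log, tag_pose(map, 0))
      sqrt((tail(traj$x, 1) - tail(drv$truth$x, 1))^2 +
             (tail(traj$y, 1) - tail(drv$truth$y, 1))^2)
    }, numeric(1))
    mean(errs)
  }
  e <- c(err_at(4), err_at(9), err_at(16))
  expect_true(all(diff(e) > 0))
})

test_that("pinhole projection: far fruit shrink, crossing time matches the schedule", {
  setup <- exact_setup()
  cam <- setup$camera
  fruit <- data.frame(x = c(4, 4.6), dist = c(setup$d, 3 * setup$d),
                      z = 0, ripe = TRUE, row = c(1L, 2L))
  stream <- render_detection_stream(fruit, cam, setup$v, c(0, 9),
                                    noise = noiseless())
  det <- stream$detections
  # unclipped boxes only: clipping at the frame edges shrinks widths
  det <- det[det$xmin > 0 & det$xmax < cam$width, , drop = FALSE]
  w_near <- max(det$xmax - det$xmin)
  w_far <- min(det$xmax - det$xmin)
  expect_equal(w_far / w_near, 1 / 3, tolerance = 0.02)
  # frames for one full crossing = width * d * fps / (fx * v) = r * i_t
  crossing <- cam$width * setup$d * cam$fps / (cam$fx * setup$v)
  r <- 4
  expect_equal(crossing,
               r * theoretical_interval(cam, setup$v, setup$d, r),
               tolerance = 1e-9)
  # the near fruit is fully interior for crossing * (1 - bbox_w / width)
  # frames: the simulator realises the schedule's geometry
  near <- det[det$xmax - det$xmin > 0.9 * w_near, ]
  interior <- near[near$xmin > 0 & near$xmax < cam$width, ]
  expect_equal(nrow(interior), crossing * (1 - w_near / cam$width),
               tolerance = 2 / crossing)
})

test_that("ground-truth accounting matches the scene", {
  setup <- exact_setup()
  stream <- exact_stream(12, setup)
  gt <- attr(stream, "ground_truth")
  expect_equal(gt$ripe, 12)
  expect_equal(gt$unripe, 0)
  # zero-noise: exactly one box per visible fruit per frame
  det <- stream$detections
  per_frame <- table(det$frame)
  fruit <- exact_fruit(12, setup)
  for (f in as.integer(names(per_frame)[c(1, length(per_frame) %/% 2)])) {
    xr <- 2 + setup$v * f / setup$camera$fps
    uc <- setup$camera$cx + setup$camera$fx * (fruit$x - xr) / fruit$dist
    hw <- setup$camera$fx * 0.015 / fruit$dist
    visible <- sum(uc + hw > 0 & uc - hw < setup$camera$width)
    expect_equal(unname(per_frame[as.character(f)]), visible)
  }
})

test_that("a full world simulation wires the modules together", {
  spec <- world_spec(tag_count = 10, fruit = make_fruit_scene(8, 4, seed = 2),
                     seed = 3)
  w <- simulate_world(spec)
  expect_s3_class(w$map, "tag_map")
  expect_s3_class(w$log, "sensor_log")
  expect_s3_class(w$stream, "detection_stream")
  expect_equal(nrow(w$map$tags), 10)
  expect_gt(nrow(w$log$observations), 0)
  expect_gt(w$stream$n_frames, 0)
})
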