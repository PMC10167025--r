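# Shared builders for synthetic test scenes.

# Camera + config calibrated so i_t = base_interval / r at speed v:
# intervals are exact integers for r in powers of two, giving schedules
# with zero extraction error.
exact_setup <- function(v = 0.25, base_interval = 32, fps = 30, ...) {
  cam <- camera_model(fx = 900, fps = fps)
  d <- base_interval * cam$fx * v / (cam$width * cam$fps)
  cfg <- counting_config(fruit_distance = d, ...)
  list(camera = cam, d = d, v = v, config = cfg)
}

# Ripe fruit placed so that every keyframe projection is mid-cell on the
# finest selected keyframe grid: each fruit lands strictly interior in
# exactly r keyframes of every power-of-two schedule.
exact_fruit <- function(n_ripe, setup, x0 = 2, u_offset = 80) {
  u0 <- seq_len(n_ripe) * 640 + u_offset
  data.frame(x = x0 + u0 * setup$d / setup$camera$fx,
             dist = setup$d, z = 0, ripe = TRUE, row = 1L)
}

exact_stream <- function(n_ripe, setup, noise = noiseless(), seed = NULL,
                         fruit_extra = NULL, x0 = 2) {
  fruit <- exact_fruit(n_ripe, setup, x0 = x0)
  if (!is.null(fruit_extra)) fruit <- rbind(fruit, fruit_extra)
  render_detection_stream(fruit, setup$camera, setup$v,
                          x_range = c(x0, max(fruit$x) + 1),
                          noise = noise, seed = seed)
}

# error of each mapped tag position against the ground-truth layout
tag_position_errors <- function(est_map, truth_map) {
  vapply(est_map$tags$id, function(id) {
    a <- tag_pose(est_map, id); b <- tag_pose(truth_map, id)
    sqrt((a[["x"]] - b[["x"]])^2 + (a[["y"]] - b[["y"]])^2)
  }, numeric(1))
}

# exhaustive fewest-hop oracle: enumerate all simple paths by DFS
brute_force_hops <- function(edges, start, goal, n) {
  adj <- lapply(0:(n - 1), function(v)
    sort(unique(c(edges$to[edges$from == v], edges$from[edges$to == v]))))
  best <- Inf
  recurse <- function(v, visited, depth) {
    if (depth >= best) return()
    if (v == goal) { best <<- depth; return() }
    for (w in adj[[v + 1]])
      if (!visited[w + 1]) {
        visited[w + 1] <- TRUE
        recurse(w, visited, depth + 1)
        visited[w + 1] <- FALSE
      }
  }
  visited <- rep(FALSE, n); visited[start + 1] <- TRUE
  recurse(start, visited, 0)
  best
}

random_connected_map <- function(n, extra_edges = 2) {
  repeat {
    perm <- sample(0:(n - 1))
    edges <- data.frame(from = perm[-n], to = perm[-1])  # random spanning tree
    if (extra_edges > 0) {
      cand <- expand.grid(from = 0:(n - 1), to = 0:(n - 1))
      cand <- cand[cand$from < cand$to, ]
      pick <- cand[sample(nrow(cand), min(extra_edges, nrow(cand))), ]
      edges <- rbind(edges, pick)
    }
    tags <- data.frame(id = 0:(n - 1), x = runif(n, 0, 10),
                       y = runif(n, 0, 10), theta = 0, virtual = FALSE)
    return(tag_map(tags, edges))
  }
}
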