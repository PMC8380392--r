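# Shared fixture builders; everything is constructed in code.

# force-frame table with constant paw layout; per-paw weights can be a
# single value, a length-4 vector (fl, fr, rl, rr) or an n x 4 matrix
make_frames <- function(n = 10, fs = 10, w = 100, abdomen = 0,
                        pos = rbind(fl = c(3.5, -2), fr = c(3.5, 2),
                                    rl = c(-3.5, -2.5), rr = c(-3.5, 2.5))) {
  paws <- c("fl", "fr", "rl", "rr")
  if (is.matrix(w)) {
    wm <- w
  } else {
    if (length(w) == 1L) w <- rep(w, 4L)
    wm <- matrix(w, n, 4L, byrow = TRUE)
  }
  df <- data.frame(t = (seq_len(n) - 1) / fs)
  for (i in seq_along(paws)) {
    df[[paste0(paws[i], "x")]] <- rep(pos[paws[i], 1L], n)
    df[[paste0(paws[i], "y")]] <- rep(pos[paws[i], 2L], n)
    df[[paste0(paws[i], "w")]] <- wm[, i]
  }
  df$abdomen_w <- rep(abdomen, length.out = n)
  force_frames(df)
}

# straight-line trajectory of the whole body at constant speed along +x
make_straight_traj <- function(speed = 5, duration = 10, fs = 20,
                               start = c(10, 40)) {
  t <- seq(0, duration, by = 1 / fs)
  x <- start[1] + speed * t
  y <- rep(start[2], length(t))
  trajectory(data.frame(t = t, nose_x = x + 5, nose_y = y,
                        center_x = x, center_y = y,
                        tail_x = x - 10, tail_y = y),
             bounds_tol = 100)
}

# circular path of the center at constant speed (counter-clockwise)
make_circle_traj <- function(radius = 10, speed = 5, laps = 1, fs = 100,
                             center = c(40, 40)) {
  omega <- speed / radius
  t <- seq(0, laps * 2 * pi / omega, by = 1 / fs)
  ang <- omega * t
  x <- center[1] + radius * cos(ang)
  y <- center[2] + radius * sin(ang)
  hd <- ang + pi / 2  # tangent direction
  trajectory(data.frame(t = t,
                        nose_x = x + 5 * cos(hd), nose_y = y + 5 * sin(hd),
                        center_x = x, center_y = y,
                        tail_x = x - 10 * cos(hd), tail_y = y - 10 * sin(hd)),
             bounds_tol = 20)
}

# trajectory with a prescribed per-sample bend angle (deg, + = left)
make_bent_traj <- function(theta_deg, n = 10, fs = 10) {
  t <- (seq_len(n) - 1) / fs
  th <- rep(theta_deg, length.out = n) * pi / 180
  cx <- 40 + t; cy <- rep(40, n)
  trajectory(data.frame(t = t,
                        nose_x = cx + 5 * cos(th), nose_y = cy + 5 * sin(th),
                        center_x = cx, center_y = cy,
                        tail_x = cx - 10, tail_y = cy))
}

# mirror a trajectory through the x axis (left <-> right flip)
mirror_traj <- function(traj) {
  d <- as.data.frame(traj)
  for (col in c("nose_y", "center_y", "tail_y")) d[[col]] <- 80 - d[[col]]
  trajectory(d)
}

# mirror force frames left <-> right (swap paw pairs, negate y)
mirror_frames <- function(frames) {
  d <- as.data.frame(frames)
  out <- d
  swap <- c(fl = "fr", fr = "fl", rl = "rr", rr = "rl")
  for (p in names(swap)) {
    for (ax in c("x", "y", "w")) {
      out[[paste0(p, ax)]] <- d[[paste0(swap[[p]], ax)]]
    }
  }
  for (p in names(swap)) {
    out[[paste0(p, "y")]] <- -out[[paste0(p, "y")]]
  }
  force_frames(out)
}

# random convex quadrilateral in fl -> fr -> rr -> rl perimeter order
random_convex_quad <- function() {
  repeat {
    pts <- matrix(runif(8, -5, 5), 4, 2)
    h <- grDevices::chull(pts)
    if (length(h) == 4) break
  }
  m <- pts[h, ]
  rownames(m) <- c("fl", "fr", "rr", "rl")   # hull order = perimeter order
  paw_quad(m[c("fl", "fr", "rl", "rr"), ])
}

triangle_area <- function(a, b, c) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c)
  abs((b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])) / 2
}

# balanced group x time measurement table with cell means `mu[g, t]`
make_table <- function(mu, n_per_cell, sd = 1, subject_effect = 0) {
  groups <- rownames(mu); tps <- colnames(mu)
  rows <- list()
  id <- 0L
  for (g in groups) {
    for (a in seq_len(n_per_cell)) {
      id <- id + 1L
      se <- rnorm(1, 0, subject_effect)
      for (tp in tps) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("s%03d", id), group = g, timepoint = tp,
          value = mu[g, tp] + se + rnorm(1, 0, sd))
      }
    }
  }
  do.call(rbind, rows)
}

# a small cohort configuration that keeps recordings short
small_cohort_config <- function(...) {
  cohort_config(
    groups = list(sham = list(n = 4L), UVN_placebo = list(n = 4L),
                  UVN_met = list(n = 4L)),
    dwb = list(duration = 30),
    openfield = list(duration = 30, fs = 10),
    ...)
}
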