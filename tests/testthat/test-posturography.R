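test_that("barycenter matches hand-worked and degenerate cases", {
  sym <- make_frames(n = 1, w = 100,
                     pos = rbind(fl = c(-1, -1), fr = c(-1, 1),
                                 rl = c(1, -1), rr = c(1, 1)))
  expect_equal(unlist(barycenter(sym)), c(barx = 0, bary = 0))

  f <- make_frames(n = 1, w = c(1, 1, 1, 3),
                   pos = rbind(fl = c(0, 0), fr = c(2, 0),
                               rl = c(0, 2), rr = c(2, 2)))
  expect_equal(unlist(barycenter(f)), c(barx = 4 / 3, bary = 4 / 3))

  one <- make_frames(n = 1, w = c(250, 0, 0, 0),
                     pos = rbind(fl = c(0, 1), fr = c(2, 0),
                                 rl = c(0, 2), rr = c(2, 2)))
  expect_equal(unlist(barycenter(one)), c(barx = 0, bary = 1))

  zero <- make_frames(n = 1, w = 0)
  expect_error(barycenter(zero), "total paw force is zero")
})

test_that("barycenter equals brute-force weighted mean and stays in hull", {
  set.seed(101)
  for (i in 1:200) {
    pos <- matrix(runif(8, -5, 5), 4, 2,
                  dimnames = list(c("fl", "fr", "rl", "rr"), NULL))
    w <- runif(4, 0.1, 300)
    fr <- make_frames(n = 1, w = w, pos = pos)
    b <- barycenter(fr)
    expect_equal(b$barx, sum(pos[, 1] * w) / sum(w))
    expect_equal(b$bary, sum(pos[, 2] * w) / sum(w))
    # inside convex hull: the barycenter of non-negative weights is a
    # convex combination, so it must lie within the bounding box too
    expect_true(b$barx >= min(pos[, 1]) && b$barx <= max(pos[, 1]))
    expect_true(b$bary >= min(pos[, 2]) && b$bary <= max(pos[, 2]))
  }
  # equal forces reduce to the unweighted centroid
  pos <- rbind(fl = c(0, 0), fr = c(4, 1), rl = c(1, 3), rr = c(5, 4))
  b <- barycenter(make_frames(n = 1, w = 80, pos = pos))
  expect_equal(unlist(b), c(barx = mean(pos[, 1]), bary = mean(pos[, 2])))
})

test_that("stance detection matches definitions on constructed recordings", {
  # constant four-paw loading for 10 s -> one epoch of 10 s
  fr <- make_frames(n = 100, fs = 10, w = 80)
  ep <- detect_stance_epochs(fr)
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration, 10)
  expect_equal(ep$n_frames, 100L)

  # alternating four-paw / rearing: only four-paw segments are returned
  w <- matrix(80, 40, 4)
  w[11:20, 1:2] <- 0   # front paws unloaded (rearing)
  w[31:40, 1:2] <- 0
  fr2 <- make_frames(n = 40, fs = 10, w = w)
  ep2 <- detect_stance_epochs(fr2)
  expect_equal(nrow(ep2), 2L)
  expect_equal(ep2$n_frames, c(10L, 10L))
  expect_true(all(ep2[, paste0(c("fl", "fr", "rl", "rr"), "w")] >= 5))
})

test_that("stance detection agrees with a frame-by-frame scan oracle", {
  set.seed(202)
  for (rep in 1:5) {
    n <- 300
    fs <- 10
    w <- matrix(runif(n * 4, 0, 40), n, 4)
    pos0 <- rbind(fl = c(3.5, -2), fr = c(3.5, 2),
                  rl = c(-3.5, -2.5), rr = c(-3.5, 2.5))
    drift <- cbind(cumsum(rnorm(n, 0, 0.08)), cumsum(rnorm(n, 0, 0.08)))
    df <- data.frame(t = (seq_len(n) - 1) / fs)
    paws <- c("fl", "fr", "rl", "rr")
    for (i in seq_along(paws)) {
      df[[paste0(paws[i], "x")]] <- pos0[i, 1] + drift[, 1]
      df[[paste0(paws[i], "y")]] <- pos0[i, 2] + drift[, 2]
      df[[paste0(paws[i], "w")]] <- w[, i]
    }
    df$abdomen_w <- 0
    fr <- force_frames(df)

    min_w <- 5; min_d <- 0.2; max_v <- 2
    ep <- detect_stance_epochs(fr, min_w, min_d, max_v)

    # oracle: literal scan over frames
    loaded <- apply(w, 1, function(z) all(z >= min_w))
    b <- t(vapply(seq_len(n), function(i) {
      if (!loaded[i]) return(c(NA_real_, NA_real_))
      bb <- barycenter(df[i, ])
      c(bb$barx, bb$bary)
    }, numeric(2)))
    runs <- list()
    cur <- integer(0)
    for (i in seq_len(n)) {
      extend <- loaded[i] && length(cur) > 0 &&
        cur[length(cur)] == i - 1 &&
        sqrt(sum((b[i, ] - b[i - 1, ])^2)) / (df$t[i] - df$t[i - 1]) <= max_v
      if (extend) {
        cur <- c(cur, i)
      } else {
        if (length(cur) > 0) runs[[length(runs) + 1]] <- cur
        cur <- if (loaded[i]) i else integer(0)
      }
    }
    if (length(cur) > 0) runs[[length(runs) + 1]] <- cur
    keep <- Filter(function(ix) {
      df$t[ix[length(ix)]] - df$t[ix[1]] + 1 / fs >= min_d - 1e-9
    }, runs)

    expect_equal(nrow(ep), length(keep))
    if (length(keep) > 0) {
      expect_equal(ep$start_t, vapply(keep, function(ix) df$t[ix[1]],
                                      numeric(1)))
      expect_equal(ep$n_frames, vapply(keep, length, integer(1)))
    }
  }
})

test_that("statokinesigram weighted mean follows epoch durations", {
  # two epochs at the same point -> mean at that point
  fr <- make_frames(n = 100, fs = 10, w = 80)
  w <- matrix(80, 100, 4); w[41:60, 1:2] <- 0
  fr2 <- make_frames(n = 100, fs = 10, w = w)
  sk <- build_statokinesigram(detect_stance_epochs(fr2))
  expect_equal(nrow(sk$points), 2L)
  expect_equal(unname(sk$mean), unname(unlist(barycenter(fr[1, ]))))

  # (0,0) for 1 s and (1,0) for 3 s -> (0.75, 0); built via epochs whose
  # barycenters sit at x = 0 and x = 1
  sq <- rbind(fl = c(-1, -1), fr = c(-1, 1), rl = c(1, -1), rr = c(1, 1))
  sq2 <- sweep(sq, 2, c(1, 0), "+")
  n1 <- 10; n2 <- 30
  df <- rbind(as.data.frame(make_frames(n = n1, fs = 10, w = 50, pos = sq)),
              as.data.frame(make_frames(n = n2, fs = 10, w = 50, pos = sq2)))
  df$t <- (seq_len(n1 + n2) - 1) / 10
  # separate the epochs with an unloaded frame
  df <- rbind(df[1:n1, ], df[n1, ], df[(n1 + 1):(n1 + n2), ])
  df$t <- (seq_len(nrow(df)) - 1) / 10
  df[n1 + 1, paste0(c("fl", "fr", "rl", "rr"), "w")] <- 0
  sk2 <- build_statokinesigram(detect_stance_epochs(force_frames(df)))
  expect_equal(nrow(sk2$points), 2L)
  expect_equal(sk2$points$duration, c(1, 3))
  expect_equal(unname(sk2$mean), c(0.75, 0))

  # permutation invariance of the weighted mean
  ep <- detect_stance_epochs(force_frames(df))
  ep_shuffled <- ep[c(2, 1), ]
  class(ep_shuffled) <- class(ep)
  expect_equal(build_statokinesigram(ep_shuffled)$mean, sk2$mean)

  # statokinesigram of zero epochs errors distinctly
  empty <- detect_stance_epochs(make_frames(n = 5, w = 1))
  expect_equal(nrow(empty), 0L)
  expect_error(build_statokinesigram(empty), "no stance epochs")
})

test_that("lateral position, inertia and deviation follow their definitions", {
  sq <- rbind(fl = c(-1, -1), fr = c(-1, 1), rl = c(1, -1), rr = c(1, 1))
  mk_sk <- function(y_shift) {
    fr <- make_frames(n = 50, fs = 10, w = 60,
                      pos = sweep(sq, 2, c(0, y_shift), "+"))
    build_statokinesigram(detect_stance_epochs(fr))
  }
  pre <- mk_sk(-0.2)
  post <- mk_sk(-0.8)
  expect_equal(mean_lateral_position(post, pre), -0.6)
  expect_equal(mean_lateral_position(pre, pre), 0)
  expect_warning(v <- mean_lateral_position(post, NULL), "baseline")
  expect_true(is.na(v))

  # all points identical -> raw inertia 0; identical recordings -> ratio 1
  expect_equal(barycenter_inertia(pre), 0)
  expect_error(barycenter_inertia(post, pre), "degenerate")

  # raw inertia of points on a unit circle with equal durations is 1 cm^2
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- data.frame(t_start = seq_along(ang), duration = 1,
                    barx = cos(ang), bary = sin(ang))
  sk_circ <- structure(list(points = pts, mean = c(barx = 0, bary = 0),
                            total_duration = 8), class = "statokinesigram")
  expect_equal(barycenter_inertia(sk_circ), 1)
  expect_equal(barycenter_inertia(sk_circ, sk_circ), 1)

  # max lateral deviation: span arithmetic, homogeneity, ratio identity
  pts2 <- pts; pts2$bary <- c(-0.5, 0.7, 0.1, 0, -0.2, 0.3, 0.6, -0.4)
  sk_span <- structure(list(points = pts2), class = "statokinesigram")
  expect_equal(max_lateral_deviation(sk_span), 1.2)
  pts3 <- pts2; pts3$bary <- 2 * pts2$bary
  sk_span2 <- structure(list(points = pts3), class = "statokinesigram")
  expect_equal(max_lateral_deviation(sk_span2), 2.4)
  expect_equal(max_lateral_deviation(sk_span2, sk_span), 2)

  # translation invariance of the raw dispersion statistics
  pts4 <- pts2
  pts4$barx <- pts4$barx + 3; pts4$bary <- pts4$bary - 1.5
  sk_shift <- structure(list(points = pts4), class = "statokinesigram")
  expect_equal(max_lateral_deviation(sk_shift), max_lateral_deviation(sk_span))
  expect_equal(vestcomp:::.sk_raw_inertia(sk_shift),
               vestcomp:::.sk_raw_inertia(sk_span))
})

test_that("laterality index is right-minus-left and mirror-antisymmetric", {
  expect_equal(laterality_index(make_frames(n = 5, w = 75)), 0)
  right <- make_frames(n = 5, w = c(0, 150, 0, 150))
  expect_equal(laterality_index(right), 300)
  mixed <- make_frames(n = 5, w = c(90, 60, 90, 60))
  expect_equal(laterality_index(mixed), -60)
  expect_equal(laterality_index(mirror_frames(mixed)),
               -laterality_index(mixed))
  expect_error(suppressWarnings(laterality_index(make_frames(n = 0))), "empty")
})

test_that("rearing fraction is the time share on hind paws only", {
  none <- make_frames(n = 20, w = 80)
  expect_equal(rearing_fraction(none), 0)
  w <- matrix(80, 80, 4)
  w[21:40, 1:2] <- 1   # 2 s of 8 s rearing
  fr <- make_frames(n = 80, fs = 10, w = w)
  expect_equal(rearing_fraction(fr), 25)
  # all four unloaded is not rearing
  w2 <- matrix(1, 10, 4)
  expect_equal(rearing_fraction(make_frames(n = 10, w = w2)), 0)
})

test_that("abdomen load subtracts the pre-operative mean", {
  pre <- make_frames(n = 10, w = 80, abdomen = 2)
  post <- make_frames(n = 10, w = 80, abdomen = 9.31)
  expect_equal(abdomen_load(post, pre), 7.31)
  expect_equal(abdomen_load(pre, pre), 0)
  zero <- make_frames(n = 10, w = 80, abdomen = 0)
  expect_equal(abdomen_load(zero, pre), -2)
  expect_warning(v <- abdomen_load(post, NULL), "baseline")
  expect_true(is.na(v))
})

test_that("circling counts completed fast laps in the requested direction", {
  expect_equal(circling_count(make_straight_traj(), 5, "left"), 0)

  # three full counter-clockwise laps at 10 cm/s (a hair more than three
  # turns, so the third heading excursion completes)
  laps3 <- make_circle_traj(radius = 5, speed = 10, laps = 3.05, fs = 50)
  expect_equal(circling_count(laps3, 5, "left"), 3)
  expect_equal(circling_count(laps3, 5, "right"), 0)

  # same path below the speed gate counts nothing
  expect_equal(circling_count(laps3, 15, "left"), 0)

  # mirror symmetry: left laps on the mirror equal right laps
  expect_equal(circling_count(mirror_traj(laps3), 5, "right"), 3)
  expect_equal(circling_count(mirror_traj(laps3), 5, "left"), 0)

  # stationary trajectory: zero, not an error
  still <- make_straight_traj(speed = 0, duration = 1, fs = 5)
  expect_equal(circling_count(still, 5, "left"), 0)
  expect_error(circling_count(still[1:2, ], 5, "left"), "3 samples")
})
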