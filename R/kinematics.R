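#' Open-field path metrics: distance, velocity, acceleration
#'
#' Computes the total distance moved (cm), the mean velocity (cm/s) and
#' the mean acceleration (cm/s^2) of the body center. Positions are
#' optionally smoothed with a boxcar filter before differencing; velocity
#' is the first finite difference and acceleration the finite difference
#' of the velocity vector, averaged as a magnitude. Masked (NA) samples
#' are excluded from the differences; with uniform sampling the mean
#' velocity equals total distance over duration.
#'
#' @param traj [trajectory()] (>= 2 samples; >= 3 for acceleration,
#'   otherwise acceleration is `NA`).
#' @param smoothing_window boxcar width in seconds applied to the center
#'   track before differentiation; `0` disables smoothing. Raw finite
#'   differences on noisy 25-30 Hz tracking inflate acceleration, hence
#'   the default.
#' @return object of class `kinematics_summary`: list with
#'   `total_distance`, `mean_velocity`, `mean_acceleration`,
#'   `mean_body_torsion` (`NA`; see [body_torsion()]), `duration`.
#' @export
path_metrics <- function(traj, smoothing_window = 0.5) {
  traj <- as.data.frame(traj)
  if (nrow(traj) < 2L) stop("path_metrics: need at least 2 samples")
  tt <- traj$t
  x <- traj$center_x
  y <- traj$center_y
  dt_med <- median(diff(tt))

  if (smoothing_window > 0 && is.finite(dt_med) && dt_med > 0) {
    k <- max(1L, round(smoothing_window / dt_med))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > 1L) {
      x <- .boxcar(x, k)
      y <- .boxcar(y, k)
    }
  }

  ok <- is.finite(x) & is.finite(y)
  pair <- ok[-length(ok)] & ok[-1L]
  dx <- diff(x)[pair]; dy <- diff(y)[pair]; dts <- diff(tt)[pair]
  disp <- sqrt(dx^2 + dy^2)
  total_distance <- sum(disp)
  duration <- tt[length(tt)] - tt[1L]
  mean_velocity <- if (sum(dts) > 0) total_distance / sum(dts) else 0

  mean_acceleration <- NA_real_
  if (nrow(traj) >= 3L) {
    vx <- dx / dts; vy <- dy / dts
    # velocity samples sit at interval midpoints; consecutive midpoints of
    # adjacent valid pairs are spaced by the mean of the two intervals
    keep <- which(pair)
    consec <- diff(keep) == 1L
    if (any(consec)) {
      i1 <- seq_along(keep)[-length(keep)][consec]
      dvx <- vx[i1 + 1L] - vx[i1]
      dvy <- vy[i1 + 1L] - vy[i1]
      dtm <- (dts[i1] + dts[i1 + 1L]) / 2
      mean_acceleration <- mean(sqrt(dvx^2 + dvy^2) / dtm)
    } else {
      mean_acceleration <- NA_real_
    }
  }

  structure(list(total_distance = total_distance,
                 mean_velocity = mean_velocity,
                 mean_acceleration = mean_acceleration,
                 mean_body_torsion = NA_real_,
                 duration = duration),
            class = "kinematics_summary")
}

.boxcar <- function(z, k) {
  # NA-tolerant centered moving average
  half <- (k - 1L) %/% 2L
  n <- length(z)
  out <- numeric(n)
  zz <- c(rep(NA_real_, half), z, rep(NA_real_, half))
  for (i in seq_len(n)) {
    win <- zz[i:(i + 2L * half)]
    out[i] <- if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }
  out
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat(sprintf(paste0("Open-field kinematics over %.1f s:\n",
                     "  total distance    %.1f cm\n",
                     "  mean velocity     %.2f cm/s\n",
                     "  mean acceleration %.2f cm/s^2\n",
                     "  mean body torsion %s\n"),
              x$duration, x$total_distance, x$mean_velocity,
              x$mean_acceleration,
              if (is.na(x$mean_body_torsion)) "(not computed)"
              else sprintf("%.2f deg", x$mean_body_torsion)))
  invisible(x)
}

#' Mean body torsion
#'
#' Per-sample signed bend angle between the tail-to-center and
#' center-to-nose vectors, averaged over the acquisition. Positive angles
#' are counter-clockwise seen from above, i.e. torsion toward the left
#' side; a mirrored trajectory flips the sign. Samples with coincident
#' points (zero-length body vectors) or missing coordinates are skipped
#' with a warning.
#'
#' @param traj [trajectory()].
#' @return mean torsion in degrees.
#' @export
body_torsion <- function(traj) {
  traj <- as.data.frame(traj)
  v1x <- traj$center_x - traj$tail_x
  v1y <- traj$center_y - traj$tail_y
  v2x <- traj$nose_x - traj$center_x
  v2y <- traj$nose_y - traj$center_y
  len1 <- sqrt(v1x^2 + v1y^2)
  len2 <- sqrt(v2x^2 + v2y^2)
  ok <- is.finite(len1) & is.finite(len2) & len1 > 0 & len2 > 0
  n_bad <- sum(!ok)
  if (n_bad > 0L) {
    warning("body_torsion: skipping ", n_bad,
            " degenerate or masked sample(s)")
  }
  if (!any(ok)) stop("body_torsion: no valid samples")
  ang <- atan2(v1x[ok] * v2y[ok] - v1y[ok] * v2x[ok],
               v1x[ok] * v2x[ok] + v1y[ok] * v2y[ok]) * 180 / pi
  mean(ang)
}

#' Baseline-normalize an open-field kinematics summary
#'
#' Locomotor quantities (distance, velocity, acceleration) are returned as
#' post/preop ratios; body torsion as the post - preop difference, the
#' normalizations conventional for these metrics.
#'
#' @param post,preop `kinematics_summary` objects (see [path_metrics()];
#'   set `mean_body_torsion` from [body_torsion()] before normalizing).
#' @return `kinematics_summary` with normalized values; a zero preop
#'   locomotor value yields `NA` with a warning.
#' @export
normalize_kinematics <- function(post, preop) {
  stopifnot(inherits(post, "kinematics_summary"),
            inherits(preop, "kinematics_summary"))
  ratio <- function(a, b, what) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    if (b == 0) {
      warning("normalize_kinematics: zero pre-operative ", what,
              "; returning NA")
      return(NA_real_)
    }
    a / b
  }
  structure(list(
    total_distance = ratio(post$total_distance, preop$total_distance,
                           "distance"),
    mean_velocity = ratio(post$mean_velocity, preop$mean_velocity,
                          "velocity"),
    mean_acceleration = ratio(post$mean_acceleration,
                              preop$mean_acceleration, "acceleration"),
    mean_body_torsion = post$mean_body_torsion - preop$mean_body_torsion,
    duration = post$duration),
    class = "kinematics_summary")
}
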