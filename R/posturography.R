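#' Force-weighted barycenter of the four paw contacts
#'
#' The barycenter is the mean paw position weighted by each paw's support
#' force:
#' \deqn{Bar_x = \frac{FL_x FL_w + FR_x FR_w + RL_x RL_w + RR_x RR_w}
#'                    {FL_w + FR_w + RL_w + RR_w}}
#' and analogously for y. It always lies inside the convex hull of the
#' four paw positions, and reduces to the unweighted centroid when all
#' forces are equal.
#'
#' @param frame a [force_frames()] table (or any data.frame carrying the
#'   paw columns); vectorized over rows.
#' @return data.frame with columns `barx`, `bary` (cm), one row per frame.
#' @export
barycenter <- function(frame) {
  frame <- as.data.frame(frame)
  w <- frame$flw + frame$frw + frame$rlw + frame$rrw
  if (any(w <= 0)) {
    stop("barycenter: total paw force is zero in row(s) ",
         paste(utils::head(which(w <= 0), 5L), collapse = ", "),
         " (barycenter undefined)")
  }
  data.frame(
    barx = (frame$flx * frame$flw + frame$frx * frame$frw +
              frame$rlx * frame$rlw + frame$rrx * frame$rrw) / w,
    bary = (frame$fly * frame$flw + frame$fry * frame$frw +
              frame$rly * frame$rlw + frame$rry * frame$rrw) / w
  )
}

#' Detect static four-paw stance epochs in a DWB recording
#'
#' An epoch is a maximal run of consecutive frames in which all four paw
#' forces stay at or above `min_paw_force` and the barycenter moves no
#' faster than `max_barycenter_speed`; runs shorter than `min_duration`
#' are discarded. These are the "static, on four paws" moments over which
#' posturographic quantities are computed.
#'
#' The representative frame of an epoch is the plain average of its member
#' frames (forces, coordinates and abdomen load), appropriate for the
#' uniformly sampled recordings the DWB device produces. Epoch duration is
#' `end_t - start_t` plus one median sampling interval, so a constant
#' recording yields its full nominal duration.
#'
#' @param frames [force_frames()] table.
#' @param min_paw_force minimum per-paw force (g) to count as loaded.
#' @param min_duration minimum epoch duration (s).
#' @param max_barycenter_speed maximum frame-to-frame barycenter speed
#'   (cm/s) tolerated inside an epoch.
#' @return data.frame of class `stance_epochs`: one row per epoch with
#'   `start_t`, `end_t`, `duration`, `n_frames` and the time-averaged
#'   frame columns (`flx` ... `abdomen_w`).
#' @export
detect_stance_epochs <- function(frames,
                                 min_paw_force = 5,
                                 min_duration = 0.2,
                                 max_barycenter_speed = 2) {
  frames <- as.data.frame(frames)
  if (nrow(frames) == 0L) stop("detect_stance_epochs: empty frame sequence")
  stopifnot(min_paw_force > 0, min_duration > 0, max_barycenter_speed > 0)
  n <- nrow(frames)
  dt_med <- if (n > 1L) median(diff(frames$t)) else min_duration

  loaded <- frames$flw >= min_paw_force & frames$frw >= min_paw_force &
    frames$rlw >= min_paw_force & frames$rrw >= min_paw_force

  # barycenter speed between consecutive loaded frames; a fast step breaks
  # the run even when both endpoints are loaded
  slow_step <- rep(FALSE, n)
  if (n > 1L) {
    idx <- which(loaded[-n] & loaded[-1L])
    if (length(idx) > 0L) {
      b <- barycenter(frames[sort(unique(c(idx, idx + 1L))), , drop = FALSE])
      pos <- matrix(NA_real_, n, 2L)
      pos[sort(unique(c(idx, idx + 1L))), ] <- as.matrix(b)
      step <- sqrt((pos[idx + 1L, 1L] - pos[idx, 1L])^2 +
                     (pos[idx + 1L, 2L] - pos[idx, 2L])^2) /
        (frames$t[idx + 1L] - frames$t[idx])
      slow_step[idx] <- step <= max_barycenter_speed
    }
  }

  # run construction: frame i extends the run of i-1 iff both loaded and
  # the connecting step is slow
  run_id <- integer(n)
  current <- 0L
  for (i in seq_len(n)) {
    if (!loaded[i]) {
      run_id[i] <- 0L
    } else if (i > 1L && run_id[i - 1L] > 0L && slow_step[i - 1L]) {
      run_id[i] <- run_id[i - 1L]
    } else {
      current <- current + 1L
      run_id[i] <- current
    }
  }

  runs <- split(seq_len(n)[run_id > 0L], run_id[run_id > 0L])
  rows <- lapply(runs, function(ix) {
    dur <- frames$t[ix[length(ix)]] - frames$t[ix[1L]] + dt_med
    if (dur < min_duration - 1e-9) return(NULL)
    rep_frame <- colMeans(frames[ix, .vc_force_cols(), drop = FALSE])
    out <- as.data.frame(as.list(rep_frame))
    out$t <- NULL
    cbind(data.frame(start_t = frames$t[ix[1L]],
                     end_t = frames$t[ix[length(ix)]],
                     duration = dur, n_frames = length(ix)),
          out)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    epochs <- data.frame(start_t = numeric(0), end_t = numeric(0),
                         duration = numeric(0), n_frames = integer(0))
    for (col in setdiff(.vc_force_cols(), "t")) epochs[[col]] <- numeric(0)
  } else {
    epochs <- do.call(rbind, rows)
    rownames(epochs) <- NULL
  }
  class(epochs) <- c("stance_epochs", "data.frame")
  epochs
}

#' Build a statokinesigram from stance epochs
#'
#' A statokinesigram is the 2-D trace of barycenter positions across the
#' static four-paw epochs of an acquisition, together with the per-paw
#' position clouds and a duration-weighted mean barycenter.
#'
#' @param epochs a `stance_epochs` table from [detect_stance_epochs()].
#' @return object of class `statokinesigram`: list with `points`
#'   (data.frame `t_start`, `duration`, `barx`, `bary`), `paws` (per-epoch
#'   mean paw positions), `mean` (duration-weighted mean barycenter,
#'   c(barx, bary)), `total_duration`.
#' @export
build_statokinesigram <- function(epochs) {
  if (!inherits(epochs, "stance_epochs")) {
    stop("build_statokinesigram: expected a stance_epochs table")
  }
  if (nrow(epochs) == 0L) {
    stop("build_statokinesigram: no stance epochs in recording")
  }
  b <- barycenter(epochs)
  pts <- data.frame(t_start = epochs$start_t, duration = epochs$duration,
                    barx = b$barx, bary = b$bary)
  w <- pts$duration / sum(pts$duration)
  paws <- epochs[, as.vector(t(outer(.vc_paws, c("x", "y"), paste0)))]
  structure(
    list(points = pts,
         paws = cbind(data.frame(t_start = epochs$start_t), paws),
         mean = c(barx = sum(w * pts$barx), bary = sum(w * pts$bary)),
         total_duration = sum(pts$duration)),
    class = "statokinesigram")
}

#' @export
print.statokinesigram <- function(x, ...) {
  cat("Statokinesigram:", nrow(x$points), "stance epochs,",
      sprintf("%.1f s total\n", x$total_duration))
  cat(sprintf("  duration-weighted mean barycenter: (%.3f, %.3f) cm\n",
              x$mean[["barx"]], x$mean[["bary"]]))
  cat(sprintf("  lateral span: [%.3f, %.3f] cm\n",
              min(x$points$bary), max(x$points$bary)))
  invisible(x)
}

#' Plot a statokinesigram
#'
#' Antero-posterior axis on the abscissa, lateral axis on the ordinate;
#' paw clouds in color, barycenter trace in green, duration-weighted mean
#' as a red dot.
#'
#' @param x `statokinesigram`.
#' @param ... passed to [plot()].
#' @export
plot.statokinesigram <- function(x, ...) {
  paw_cols <- c(fl = "pink", fr = "lightblue", rl = "red", rr = "darkblue")
  xs <- c(x$points$barx, unlist(x$paws[paste0(.vc_paws, "x")]))
  ys <- c(x$points$bary, unlist(x$paws[paste0(.vc_paws, "y")]))
  plot(NA, xlim = range(xs), ylim = range(ys),
       xlab = "antero-posterior (cm)", ylab = "lateral (cm)", ...)
  for (p in .vc_paws) {
    points(x$paws[[paste0(p, "x")]], x$paws[[paste0(p, "y")]],
           col = paw_cols[[p]], pch = 16, cex = 0.5)
  }
  points(x$points$barx, x$points$bary, col = "darkgreen", pch = 16, cex = 0.6)
  points(x$mean[["barx"]], x$mean[["bary"]], col = "red", pch = 3, lwd = 2)
  invisible(x)
}

.sk_weighted_mean_bary <- function(sk) {
  w <- sk$points$duration / sum(sk$points$duration)
  sum(w * sk$points$bary)
}

#' Mean lateral barycenter position, baseline-normalized
#'
#' Duration-weighted mean lateral (y) barycenter position of an
#' acquisition minus the animal's pre-operative value. Positive values are
#' rightward, negative leftward displacements.
#'
#' @param sk post-operative [build_statokinesigram()] result.
#' @param preop_sk pre-operative statokinesigram, or `NULL` if the animal
#'   has no baseline (result is `NA` with a warning; never imputed).
#' @return displacement in cm.
#' @export
mean_lateral_position <- function(sk, preop_sk) {
  if (is.null(preop_sk)) {
    warning("mean_lateral_position: no pre-operative baseline; returning NA")
    return(NA_real_)
  }
  .sk_weighted_mean_bary(sk) - .sk_weighted_mean_bary(preop_sk)
}

.sk_raw_inertia <- function(sk) {
  w <- sk$points$duration / sum(sk$points$duration)
  mx <- sum(w * sk$points$barx)
  my <- sum(w * sk$points$bary)
  sum(w * ((sk$points$barx - mx)^2 + (sk$points$bary - my)^2))
}

#' Barycenter inertia (dispersion of the barycenter trace)
#'
#' Raw inertia is the duration-weighted mean squared Euclidean distance of
#' the barycenter points from their duration-weighted mean (cm^2) -- the
#' trace of the weighted covariance, a rotation-invariant dispersion. With
#' a pre-operative statokinesigram the value is returned as the
#' post/preop ratio (dimensionless), the normalization used for this
#' metric.
#'
#' @param sk post-operative statokinesigram.
#' @param preop_sk pre-operative statokinesigram, or `NULL` to return the
#'   raw inertia in cm^2.
#' @return ratio (or cm^2 when `preop_sk` is `NULL`).
#' @export
barycenter_inertia <- function(sk, preop_sk = NULL) {
  raw <- .sk_raw_inertia(sk)
  if (is.null(preop_sk)) return(raw)
  pre <- .sk_raw_inertia(preop_sk)
  if (pre <= 0) {
    stop("barycenter_inertia: degenerate pre-operative baseline (zero inertia)")
  }
  raw / pre
}

#' Maximum lateral deviation of the barycenter
#'
#' Raw value is max(Bary) - min(Bary) over the statokinesigram (cm, >= 0),
#' an indicator of lateral instability; with a baseline it is returned as
#' the post/preop ratio.
#'
#' @inheritParams barycenter_inertia
#' @return ratio (or cm when `preop_sk` is `NULL`).
#' @export
max_lateral_deviation <- function(sk, preop_sk = NULL) {
  raw <- max(sk$points$bary) - min(sk$points$bary)
  if (is.null(preop_sk)) return(raw)
  pre <- max(preop_sk$points$bary) - min(preop_sk$points$bary)
  if (pre <= 0) {
    stop("max_lateral_deviation: degenerate pre-operative baseline (zero span)")
  }
  raw / pre
}

#' Weight laterality index
#'
#' Time-averaged difference between the weight on the right paws and the
#' weight on the left paws, in grams. Positive = right-loaded; after a
#' left-sided lesion the index drifts negative.
#'
#' @param frames [force_frames()] table.
#' @return grams.
#' @export
laterality_index <- function(frames) {
  frames <- as.data.frame(frames)
  if (nrow(frames) == 0L) stop("laterality_index: empty frame sequence")
  mean((frames$frw + frames$rrw) - (frames$flw + frames$rlw))
}

#' Rearing time fraction
#'
#' Percent of the recording spent on the two hind paws: both front-paw
#' forces below `min_paw_force` and both hind-paw forces at or above it.
#'
#' @param frames [force_frames()] table (uniformly sampled).
#' @param min_paw_force loaded-paw threshold (g).
#' @return percent of recording time.
#' @export
rearing_fraction <- function(frames, min_paw_force = 5) {
  frames <- as.data.frame(frames)
  if (nrow(frames) == 0L) stop("rearing_fraction: empty frame sequence")
  rearing <- frames$flw < min_paw_force & frames$frw < min_paw_force &
    frames$rlw >= min_paw_force & frames$rrw >= min_paw_force
  100 * mean(rearing)
}

#' Abdomen load, baseline-normalized
#'
#' Time-averaged abdomen-sensor force (g) minus the animal's pre-operative
#' value; an increase reflects the abdomen-contact postural strategy seen
#' after vestibular lesion. May be negative.
#'
#' @param frames post-operative [force_frames()] table.
#' @param preop_frames pre-operative table, or `NULL` (result `NA` with a
#'   warning).
#' @return grams (difference from baseline).
#' @export
abdomen_load <- function(frames, preop_frames) {
  frames <- as.data.frame(frames)
  if (nrow(frames) == 0L) stop("abdomen_load: empty frame sequence")
  if (is.null(preop_frames)) {
    warning("abdomen_load: no pre-operative baseline; returning NA")
    return(NA_real_)
  }
  mean(frames$abdomen_w) - mean(as.data.frame(preop_frames)$abdomen_w)
}

.wrap180 <- function(a) {
  ((a + 180) %% 360) - 180
}

#' Count fast circling laps in a trajectory
#'
#' Counts completed 360-degree cumulative-heading excursions of the body
#' center in the requested direction, restricted to stretches where the
#' instantaneous speed stays at or above `min_speed` ("fast laps").
#' Heading is taken from the center-point displacement vector and
#' unwrapped; left = counter-clockwise seen from above. Partial laps are
#' not counted. A stationary trajectory yields 0.
#'
#' @param traj [trajectory()] (>= 3 samples).
#' @param min_speed speed gate in cm/s.
#' @param direction `"left"` (counter-clockwise) or `"right"`.
#' @return integer lap count.
#' @export
circling_count <- function(traj, min_speed = 5, direction = c("left", "right")) {
  direction <- match.arg(direction)
  traj <- as.data.frame(traj)
  if (nrow(traj) < 3L) stop("circling_count: need at least 3 samples")
  ok <- is.finite(traj$center_x) & is.finite(traj$center_y)
  x <- traj$center_x; y <- traj$center_y; tt <- traj$t
  dx <- diff(x); dy <- diff(y); dt <- diff(tt)
  disp <- sqrt(dx^2 + dy^2)
  fast <- ok[-length(ok)] & ok[-1L] & (disp / dt >= min_speed)
  fast[is.na(fast)] <- FALSE
  heading <- atan2(dy, dx) * 180 / pi

  sgn <- if (direction == "left") 1 else -1
  laps <- 0L
  # contiguous runs of fast steps; heading deltas are unwrapped within a run
  run_start <- which(fast & !c(FALSE, fast[-length(fast)]))
  run_end <- which(fast & !c(fast[-1L], FALSE))
  for (r in seq_along(run_start)) {
    ix <- run_start[r]:run_end[r]
    if (length(ix) < 2L) next
    d <- sgn * .wrap180(diff(heading[ix]))
    cum <- cumsum(d)
    ref <- 0
    for (ci in cum) {
      if (ci - ref >= 360) {
        k <- floor((ci - ref) / 360)
        laps <- laps + k
        ref <- ref + 360 * k
      }
      if (ci < ref) ref <- ci
    }
  }
  laps
}
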