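#' Synthetic-cohort configuration
#'
#' Parameters of the synthetic unilateral-vestibular-lesion cohort. The
#' defaults describe the study conditions the generator emulates: three
#' groups (sham n = 21, lesion + placebo n = 21, lesion + treated n = 19),
#' eight acquisition time points (preop, d1, d2, d3, d7, d14, d21, d30),
#' an acute syndrome peaking in the first days that decays exponentially
#' with a group-specific rate (slowest, with the highest residual plateau,
#' in the treated group), leftward weight and torsion bias, abdomen
#' contact, acute circling bouts, acute hypo- then late hyper-locomotion,
#' and fluorescence images with membrane rings and punctate nuclei.
#'
#' @param ... named overrides merged recursively over the defaults.
#' @return nested configuration list (see source for the full field
#'   inventory); `groups` carries per-group syndrome kinetics
#'   (`s0` peak intensity, `lambda` recovery rate per day, `s_inf`
#'   residual plateau).
#' @export
cohort_config <- function(...) {
  cfg <- list(
    seed = 1L,
    groups = list(
      sham = list(n = 21L, s0 = 0, lambda = 0, s_inf = 0, lesioned = FALSE),
      UVN_placebo = list(n = 21L, s0 = 0.90, lambda = 0.30, s_inf = 0.10,
                         lesioned = TRUE),
      UVN_met = list(n = 19L, s0 = 0.95, lambda = 0.12, s_inf = 0.22,
                     lesioned = TRUE)
    ),
    timepoints = c(preop = 0, d1 = 1, d2 = 2, d3 = 3, d7 = 7, d14 = 14,
                   d21 = 21, d30 = 30),
    animal_sd = 0.06,   # per-animal random effect on the latent intensity
    dwb = list(
      fs = 10, duration = 300, body_weight = 300,
      lat_shift = 0.10,      # left-paw weight fraction shift per unit s
      abdomen_base = 2, abdomen_gain = 20, abdomen_sd = 2,
      rear_base = 0.5,       # sham rearing-time fraction
      rear_drop = 0.8, p_locomote = 0.2, seg_mean = 2,
      wander_base = 0.02, wander_gain = 0.05,  # cm/frame body sway
      reposition_sd = 0.5, reposition_gain = 1.0,  # cm between-stance shifts
      force_cv = 0.02
    ),
    openfield = list(
      fs = 25, duration = 600, arena = c(80, 80),
      speed_base = 8, speed_acute_drop = 0.7, hyper_gain = 0.5,
      torsion_gain = 13, torsion_sd = 8,   # deg
      circle_rate = 12,   # bouts per acquisition at s = 1 (acute only)
      bout_speed = 18, bout_omega = 270, bout_duration = 1.5,
      heading_sd = 60,    # deg/sqrt(s) heading diffusion
      dropout_rate = 0.002
    ),
    support = list(n_trials = 10L, base_l = 7, base_w = 4.5,
                   gain = 1.4, trial_cv = 0.12, jitter = 0.2),
    checklist = list(
      thresholds = c(tumbling = 0.85, retropulsion = 0.70, circling = 0.50,
                     bobbing = 0.35, head_tilt = 0.15),
      noise_sd = 0.07),
    cells = list(
      n_sacrificed = 4L, count_cv = 0.15, sections = c(8L, 12L),
      # group x day target mean counts (rows sham / placebo / treated)
      markers = list(
        IBA1 = rbind(sham = c(d3 = 8, d30 = 8),
                     UVN_placebo = c(d3 = 46.8, d30 = 36.1),
                     UVN_met = c(d3 = 8.33, d30 = 13.9)),
        GFAP = rbind(sham = c(d3 = 12, d30 = 12),
                     UVN_placebo = c(d3 = 49.6, d30 = 34.1),
                     UVN_met = c(d3 = 16.1, d30 = 16)),
        BrdU = rbind(sham = c(d3 = 0.5, d30 = 0.5),
                     UVN_placebo = c(d3 = 31.7, d30 = 29.9),
                     UVN_met = c(d3 = 20.6, d30 = 2.13)),
        GR = rbind(sham = c(d3 = 40, d30 = 40),
                   UVN_placebo = c(d3 = 65.3, d30 = 55),
                   UVN_met = c(d3 = 44.8, d30 = 45)))),
    images = list(
      size = 128L, bg_mean = 10, bg_sd = 2,
      ring_radius = 6, ring_thickness = 2, n_rings = 8L,
      # membrane-intensity targets per group x day
      membrane = rbind(sham = c(d3 = 60, d30 = 60),
                       UVN_placebo = c(d3 = 45, d30 = 58),
                       UVN_met = c(d3 = 75, d30 = 70)),
      blob_amp = 120, blob_sigma = 1.6, blob_min_sep = 8)
  )
  dots <- list(...)
  if (length(dots) > 0L) cfg <- modifyList(cfg, dots)
  for (g in names(cfg$groups)) {
    p <- cfg$groups[[g]]
    if (p$s_inf > p$s0 || p$lambda < 0) {
      stop("cohort_config: group '", g,
           "' must satisfy s_inf <= s0 and lambda >= 0")
    }
  }
  if (cfg$animal_sd < 0) stop("cohort_config: animal_sd must be >= 0")
  cfg
}

#' Latent syndrome intensity over post-operative time
#'
#' Exponential-recovery kinetics: `s(t) = s_inf + (s0 - s_inf) *
#' exp(-lambda * t)` for post-operative days `t >= 1`, 0 pre-operatively,
#' and identically 0 for non-lesioned (sham) parameters. `s` is a
#' dimensionless intensity in \[0, 1\] that every behavioral readout of
#' the generator is monotonically linked to.
#'
#' @param t_days post-operative day (0 or negative = pre-operative);
#'   vectorized.
#' @param s0 peak intensity in \[0, 1\].
#' @param lambda recovery rate per day (>= 0).
#' @param s_inf residual plateau (<= `s0`).
#' @return intensity in \[0, 1\].
#' @export
syndrome_intensity <- function(t_days, s0, lambda, s_inf = 0) {
  stopifnot(s_inf <= s0, lambda >= 0)
  ifelse(t_days <= 0, 0, s_inf + (s0 - s_inf) * exp(-lambda * t_days))
}

.reflect <- function(z, lo, hi) {
  # fold coordinates into [lo, hi] (billiard reflection)
  width <- hi - lo
  z <- (z - lo) %% (2 * width)
  lo + ifelse(z > width, 2 * width - z, z)
}

.unit <- function(deg) cbind(cos(deg * pi / 180), sin(deg * pi / 180))

#' Generate one DWB force recording for a latent intensity
#'
#' Alternates stance, rearing and locomotion segments; during stance the
#' four paws carry the body weight with a leftward bias proportional to
#' `s`, the body sways (barycenter dispersion grows with `s`) and the
#' abdomen sensor reads a load increasing with `s`. Rearing probability
#' decreases with `s`.
#'
#' @param s latent syndrome intensity in \[0, 1\].
#' @param cfg the `dwb` sublist of [cohort_config()].
#' @param seed integer seed.
#' @return a [force_frames()] table.
#' @export
gen_dwb_recording <- function(s, cfg, seed) {
  set.seed(seed)
  fs <- cfg$fs
  n <- round(fs * cfg$duration)
  dt <- 1 / fs
  tt <- (seq_len(n) - 1L) * dt

  n_seg_max <- ceiling(cfg$duration / cfg$seg_mean) * 3L + 10L
  seg_len <- pmax(1L, round(rexp(n_seg_max, 1 / cfg$seg_mean) * fs))
  seg_id <- rep(seq_along(seg_len), seg_len)[seq_len(n)]
  n_seg <- max(seg_id)
  p_rear <- cfg$rear_base * (1 - cfg$rear_drop * s)
  p_stance <- max(0, 1 - p_rear - cfg$p_locomote)
  seg_type <- sample(c("rear", "loco", "stance"), n_seg, replace = TRUE,
                     prob = c(p_rear, cfg$p_locomote, p_stance))
  type <- seg_type[seg_id]

  paw_nom <- rbind(fl = c(3.5, -2), fr = c(3.5, 2),
                   rl = c(-3.5, -2.5), rr = c(-3.5, 2.5))

  # body placement: per-segment repositioning plus slow within-segment sway
  rep_sd <- cfg$reposition_sd * (1 + cfg$reposition_gain * s)
  seg_off <- cbind(rnorm(n_seg, 0, rep_sd), rnorm(n_seg, 0, rep_sd))
  sway_sd <- cfg$wander_base + cfg$wander_gain * s
  sway <- cbind(rnorm(n, 0, sway_sd), rnorm(n, 0, sway_sd))
  new_seg <- c(TRUE, seg_id[-1L] != seg_id[-n])
  sway[new_seg, ] <- 0
  sway <- apply(sway, 2L, function(col) {
    stats::ave(col, cumsum(new_seg), FUN = cumsum)
  })
  body <- seg_off[seg_id, , drop = FALSE] + sway

  w_total <- cfg$body_weight
  f_left <- 0.5 + cfg$lat_shift * s
  front <- 0.4
  nom_w <- c(fl = w_total * front * f_left,
             fr = w_total * front * (1 - f_left),
             rl = w_total * (1 - front) * f_left,
             rr = w_total * (1 - front) * (1 - f_left))

  frames <- data.frame(t = tt)
  for (p in .vc_paws) {
    jitter <- cbind(rnorm(n, 0, 0.02), rnorm(n, 0, 0.02))
    frames[[paste0(p, "x")]] <- paw_nom[p, 1L] + body[, 1L] + jitter[, 1L]
    frames[[paste0(p, "y")]] <- paw_nom[p, 2L] + body[, 2L] + jitter[, 2L]
    frames[[paste0(p, "w")]] <- nom_w[[p]] * rlnorm(n, 0, cfg$force_cv)
  }
  rear <- type == "rear"
  frames$flw[rear] <- runif(sum(rear), 0, 2)
  frames$frw[rear] <- runif(sum(rear), 0, 2)
  frames$rlw[rear] <- w_total * f_left * rlnorm(sum(rear), 0, cfg$force_cv)
  frames$rrw[rear] <- w_total * (1 - f_left) * rlnorm(sum(rear), 0, cfg$force_cv)

  loco <- which(type == "loco")
  if (length(loco) > 0L) {
    swing <- sample(.vc_paws, length(loco), replace = TRUE)
    for (p in .vc_paws) {
      sel <- loco[swing == p]
      frames[[paste0(p, "w")]][sel] <- runif(length(sel), 0, 2)
      # fast limb repositioning breaks the static criterion
      frames[[paste0(p, "x")]][loco] <-
        frames[[paste0(p, "x")]][loco] + rnorm(length(loco), 0, 0.8)
      frames[[paste0(p, "y")]][loco] <-
        frames[[paste0(p, "y")]][loco] + rnorm(length(loco), 0, 0.8)
    }
  }

  frames$abdomen_w <- pmax(0, rnorm(n, cfg$abdomen_base + cfg$abdomen_gain * s,
                                    cfg$abdomen_sd))
  force_frames(frames)
}

#' Generate one open-field trajectory for a latent intensity
#'
#' Random-walk locomotion with heading diffusion; speed is suppressed in
#' proportion to `s` during the acute phase and elevated late after
#' lesion (hyperactivity); fast counter-clockwise circling bouts occur at
#' a rate proportional to `s` during the acute days; body torsion (the
#' tail-center-nose bend) is leftward-biased in proportion to `s`.
#'
#' @param s latent syndrome intensity.
#' @param day post-operative day (0 = preop).
#' @param lesioned logical.
#' @param cfg the `openfield` sublist of [cohort_config()].
#' @param seed integer seed.
#' @return a [trajectory()].
#' @export
gen_trajectory <- function(s, day, lesioned, cfg, seed) {
  set.seed(seed)
  fs <- cfg$fs
  n <- round(fs * cfg$duration)
  dt <- 1 / fs

  hyper <- cfg$hyper_gain * (1 - exp(-max(0, day - 3) / 10)) * lesioned
  mult <- max(0.05, 1 - cfg$speed_acute_drop * s + hyper)
  speed <- pmax(0.2, cfg$speed_base * mult + rnorm(n, 0, 1.5))
  dphi <- rnorm(n, 0, cfg$heading_sd * sqrt(dt))

  acute <- day >= 1 && day <= 3
  if (acute && s > 0) {
    n_bouts <- rpois(1L, cfg$circle_rate * s * cfg$duration / 600)
    if (n_bouts > 0L) {
      bout_len <- round(cfg$bout_duration * fs)
      starts <- sort(sample.int(max(1L, n - bout_len), n_bouts))
      for (b in starts) {
        ix <- b:min(n, b + bout_len - 1L)
        dphi[ix] <- cfg$bout_omega * dt   # counter-clockwise = leftward
        speed[ix] <- cfg$bout_speed
      }
    }
  }

  phi <- cumsum(dphi)
  u <- .unit(phi)
  lo <- 12; hix <- cfg$arena[1L] - 12; hiy <- cfg$arena[2L] - 12
  cx <- .reflect(cfg$arena[1L] / 2 + cumsum(speed * dt * u[, 1L]), lo, hix)
  cy <- .reflect(cfg$arena[2L] / 2 + cumsum(speed * dt * u[, 2L]), lo, hiy)

  theta <- cfg$torsion_gain * s + rnorm(n, 0, cfg$torsion_sd)
  un <- .unit(phi + theta)
  nose_x <- cx + 5 * un[, 1L]; nose_y <- cy + 5 * un[, 2L]
  tail_x <- cx - 10 * u[, 1L]; tail_y <- cy - 10 * u[, 2L]

  drop <- runif(n) < cfg$dropout_rate
  nose_x[drop] <- NA_real_; nose_y[drop] <- NA_real_

  trajectory(data.frame(t = (seq_len(n) - 1L) * dt,
                        nose_x = nose_x, nose_y = nose_y,
                        center_x = cx, center_y = cy,
                        tail_x = tail_x, tail_y = tail_y),
             arena_size = cfg$arena)
}

#' Generate landing paw quads for one support-surface session
#'
#' Quadrilateral paw placements whose expected area is inflated by the
#' factor `1 + gain * s`, with per-trial multiplicative noise and corner
#' jitter.
#'
#' @param s latent syndrome intensity.
#' @param cfg the `support` sublist of [cohort_config()].
#' @param seed integer seed.
#' @return list of [paw_quad()] matrices (one per trial).
#' @export
gen_paw_quads <- function(s, cfg, seed) {
  set.seed(seed)
  scale <- sqrt(1 + cfg$gain * s)
  lapply(seq_len(cfg$n_trials), function(i) {
    trial <- sqrt(rlnorm(1L, 0, cfg$trial_cv))
    l <- cfg$base_l * scale * trial / 2
    w <- cfg$base_w * scale * trial / 2
    m <- rbind(fl = c(l, -w), fr = c(l, w),
               rl = c(-l, -w), rr = c(-l, w)) +
      matrix(rnorm(8L, 0, cfg$jitter), 4L, 2L)
    paw_quad(m)
  })
}

#' Generate a symptom checklist for a latent intensity
#'
#' Each symptom turns on when `s` plus small observation noise exceeds a
#' fixed severity threshold, ordered as on the cumulative scale (tumbling
#' requires the most severe syndrome, head tilt the least).
#'
#' @param s latent syndrome intensity.
#' @param cfg the `checklist` sublist of [cohort_config()].
#' @param seed integer seed.
#' @return named logical vector (tumbling, retropulsion, circling,
#'   bobbing, head_tilt).
#' @export
gen_checklist <- function(s, cfg, seed) {
  set.seed(seed)
  thr <- cfg$thresholds
  obs <- s + rnorm(length(thr), 0, cfg$noise_sd)
  setNames(obs > thr, names(thr))
}

#' Generate per-section cell counts around a target mean
#'
#' @param target_mean target mean count for the animal.
#' @param cfg the `cells` sublist of [cohort_config()].
#' @param seed integer seed.
#' @return integer vector of per-section counts (8-12 sections).
#' @export
gen_cell_counts <- function(target_mean, cfg, seed) {
  set.seed(seed)
  n_sec <- sample(seq(cfg$sections[1L], cfg$sections[2L]), 1L)
  pmax(0L, as.integer(round(rnorm(n_sec, target_mean,
                                  cfg$count_cv * target_mean + 0.5))))
}

#' Synthetic membrane-fluorescence image with ring-shaped cells
#'
#' Places non-overlapping annular membrane rings of given intensities on a
#' Gaussian background and returns the image together with the exact ROI
#' set (per-ring membrane masks and a background rectangle kept free of
#' rings), so that membrane quantification can be validated against the
#' planted truth.
#'
#' @param intensities numeric vector, one constant ring intensity per
#'   cell.
#' @param cfg the `images` sublist of [cohort_config()].
#' @param seed integer seed.
#' @return list with `image` ([image_grid()]), `rois` (list `background`,
#'   `membranes` as pixel index vectors), `intensities`.
#' @export
gen_membrane_image <- function(intensities, cfg, seed) {
  set.seed(seed)
  size <- cfg$size
  img <- matrix(pmax(0, rnorm(size * size, cfg$bg_mean, cfg$bg_sd)),
                size, size)
  r <- cfg$ring_radius; th <- cfg$ring_thickness
  bg_rect <- c(1L, 24L)  # rows/cols 1..24 reserved for the background ROI
  margin <- r + th + 2
  centers <- matrix(NA_real_, length(intensities), 2L)
  k <- 0L
  while (k < length(intensities)) {
    cand <- c(runif(1L, 30 + margin, size - margin),
              runif(1L, margin, size - margin))
    if (k > 0L) {
      dmin <- min(sqrt(rowSums(sweep(centers[seq_len(k), , drop = FALSE],
                                     2L, cand)^2)))
      if (dmin < 2 * (r + th)) next
    }
    k <- k + 1L
    centers[k, ] <- cand
  }
  rows <- row(img); cols <- col(img)
  membranes <- vector("list", length(intensities))
  for (i in seq_along(intensities)) {
    d <- sqrt((rows - centers[i, 1L])^2 + (cols - centers[i, 2L])^2)
    mask <- which(d >= r - th / 2 & d <= r + th / 2)
    img[mask] <- intensities[i]
    membranes[[i]] <- mask
  }
  background <- which(rows <= bg_rect[2L] & cols <= bg_rect[2L])
  list(image = image_grid(img),
       rois = list(background = background, membranes = membranes),
       intensities = intensities, centers = centers)
}

#' Synthetic nuclei image with well-separated Gaussian blobs
#'
#' @param n_blobs number of planted cells.
#' @param cfg the `images` sublist of [cohort_config()].
#' @param seed integer seed.
#' @return list with `image`, `centers` (n x 2, row/col), `n_blobs`.
#' @export
gen_nuclei_image <- function(n_blobs, cfg, seed) {
  set.seed(seed)
  size <- cfg$size
  img <- matrix(pmax(0, rnorm(size * size, cfg$bg_mean, cfg$bg_sd)),
                size, size)
  centers <- matrix(NA_real_, n_blobs, 2L)
  margin <- 4 * cfg$blob_sigma
  k <- 0L
  tries <- 0L
  while (k < n_blobs && tries < 20000L) {
    tries <- tries + 1L
    cand <- runif(2L, margin, size - margin)
    if (k > 0L) {
      dmin <- min(sqrt(rowSums(sweep(centers[seq_len(k), , drop = FALSE],
                                     2L, cand)^2)))
      if (dmin < cfg$blob_min_sep) next
    }
    k <- k + 1L
    centers[k, ] <- cand
  }
  if (k < n_blobs) stop("gen_nuclei_image: could not place all blobs")
  rows <- row(img); cols <- col(img)
  for (i in seq_len(n_blobs)) {
    d2 <- (rows - centers[i, 1L])^2 + (cols - centers[i, 2L])^2
    img <- img + cfg$blob_amp * exp(-d2 / (2 * cfg$blob_sigma^2))
  }
  list(image = image_grid(img), centers = centers, n_blobs = n_blobs)
}

#' Simulate a complete synthetic cohort
#'
#' Draws a latent syndrome intensity for every animal x timepoint (group
#' kinetics plus a per-animal random effect, truncated to \[0, 1\]) and
#' emits the requested data components: DWB force streams, open-field
#' trajectories, landing paw quads, symptom checklists, per-section cell
#' counts and fluorescence images. Fully reproducible: the same config
#' and seed give an identical dataset, and the random substream of each
#' record is fixed up front so that generating a subset of components
#' does not change the others.
#'
#' @param config a [cohort_config()].
#' @param components character subset of `c("checklists", "quads", "dwb",
#'   "trajectories", "cells", "images")`.
#' @return object of class `vc_cohort`: list with `records` (animal x
#'   timepoint table with the latent `s`), `checklists`, `quads`, `dwb`,
#'   `trajectories`, `cells`, `images`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            components = c("checklists", "quads", "dwb",
                                           "trajectories", "cells",
                                           "images")) {
  components <- match.arg(components, several.ok = TRUE,
                          choices = c("checklists", "quads", "dwb",
                                      "trajectories", "cells", "images"))
  groups <- config$groups
  tps <- config$timepoints

  animals <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(animal_id = sprintf("%s_%02d", g, seq_len(groups[[g]]$n)),
               group = g)
  }))

  records <- merge(animals,
                   data.frame(timepoint = names(tps), day = unname(tps)),
                   by = NULL)
  records <- records[order(match(records$animal_id, animals$animal_id),
                           records$day), ]
  rownames(records) <- NULL

  set.seed(config$seed)
  re <- setNames(rnorm(nrow(animals), 0, config$animal_sd),
                 animals$animal_id)
  seed_pool <- 2147483646
  comp_names <- c("dwb", "trajectories", "quads", "checklists")
  seed_mat <- matrix(sample.int(seed_pool, nrow(records) * length(comp_names)),
                     nrow(records), length(comp_names),
                     dimnames = list(NULL, comp_names))
  cell_seed <- sample.int(seed_pool, 1L)
  image_seed <- sample.int(seed_pool, 1L)

  s <- vapply(seq_len(nrow(records)), function(i) {
    g <- groups[[records$group[i]]]
    base <- syndrome_intensity(records$day[i], g$s0, g$lambda, g$s_inf)
    if (g$lesioned && records$day[i] > 0) {
      min(1, max(0, base + re[[records$animal_id[i]]]))
    } else base
  }, numeric(1L))
  records$s <- s
  key <- paste(records$animal_id, records$timepoint, sep = ".")

  out <- list(records = records, config = config)

  if ("checklists" %in% components) {
    cl <- t(vapply(seq_len(nrow(records)), function(i) {
      gen_checklist(records$s[i], config$checklist, seed_mat[i, "checklists"])
    }, logical(5L)))
    out$checklists <- cbind(records[c("animal_id", "group", "timepoint",
                                      "day")],
                            as.data.frame(cl))
  }
  if ("quads" %in% components) {
    out$quads <- setNames(lapply(seq_len(nrow(records)), function(i) {
      gen_paw_quads(records$s[i], config$support, seed_mat[i, "quads"])
    }), key)
  }
  if ("dwb" %in% components) {
    out$dwb <- setNames(lapply(seq_len(nrow(records)), function(i) {
      gen_dwb_recording(records$s[i], config$dwb, seed_mat[i, "dwb"])
    }), key)
  }
  if ("trajectories" %in% components) {
    out$trajectories <- setNames(lapply(seq_len(nrow(records)), function(i) {
      gen_trajectory(records$s[i], records$day[i],
                     groups[[records$group[i]]]$lesioned,
                     config$openfield, seed_mat[i, "trajectories"])
    }), key)
  }
  if ("cells" %in% components) {
    set.seed(cell_seed)
    rows <- list()
    for (marker in names(config$cells$markers)) {
      targets <- config$cells$markers[[marker]]
      for (g in rownames(targets)) {
        for (d in colnames(targets)) {
          for (a in seq_len(config$cells$n_sacrificed)) {
            sec_seed <- sample.int(seed_pool, 1L)
            counts <- gen_cell_counts(targets[g, d], config$cells, sec_seed)
            rows[[length(rows) + 1L]] <- data.frame(
              marker = marker, group = g, day = d,
              animal_id = sprintf("%s_%s_sac%02d", g, d, a),
              section = seq_along(counts), count = counts)
          }
        }
      }
    }
    out$cells <- do.call(rbind, rows)
  }
  if ("images" %in% components) {
    set.seed(image_seed)
    membrane <- list()
    counting <- list()
    mem_targets <- config$images$membrane
    iba <- config$cells$markers$IBA1
    for (g in rownames(mem_targets)) {
      for (d in colnames(mem_targets)) {
        for (a in seq_len(config$cells$n_sacrificed)) {
          s1 <- sample.int(seed_pool, 1L)
          s2 <- sample.int(seed_pool, 1L)
          ints <- pmax(5, rnorm(config$images$n_rings, mem_targets[g, d],
                                0.08 * mem_targets[g, d]))
          id <- sprintf("%s_%s_sac%02d", g, d, a)
          membrane[[id]] <- gen_membrane_image(ints, config$images, s1)
          n_blobs <- max(0L, as.integer(round(iba[g, d] / 4)))
          if (n_blobs > 0L) {
            counting[[id]] <- gen_nuclei_image(n_blobs, config$images, s2)
          }
        }
      }
    }
    out$images <- list(membrane = membrane, counting = counting)
  }

  class(out) <- "vc_cohort"
  out
}

#' @export
print.vc_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$records), "records (",
      length(unique(x$records$animal_id)), "animals x",
      length(x$config$timepoints), "timepoints )\n")
  cat("  components:",
      paste(intersect(c("checklists", "quads", "dwb", "trajectories",
                        "cells", "images"), names(x)), collapse = ", "),
      "\n")
  invisible(x)
}
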