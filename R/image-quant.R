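#' Support surface delimited by the four paw pads
#'
#' Shoelace (polygon) area of the quadrilateral formed by the four paw-pad
#' centroids taken in perimeter order FL -> FR -> RR -> RL, in cm^2. The
#' area is orientation-independent (absolute value); degenerate quads
#' (duplicated or collinear points) give 0 with a warning.
#'
#' @param quad data.frame or matrix with rows named `fl`, `fr`, `rl`, `rr`
#'   and columns `x`, `y` (cm); see [paw_quad()].
#' @return area in cm^2.
#' @export
support_surface <- function(quad) {
  quad <- paw_quad(quad)
  ord <- c("fl", "fr", "rr", "rl")
  x <- quad[ord, "x"]; y <- quad[ord, "y"]
  i2 <- c(2L, 3L, 4L, 1L)
  area <- abs(sum(x * y[i2] - x[i2] * y)) / 2
  if (area == 0) {
    warning("support_surface: degenerate quadrilateral (area 0)")
  }
  area
}

#' Validate a labeled paw quadrilateral
#'
#' @param quad matrix/data.frame with rows `fl`, `fr`, `rl`, `rr` and
#'   columns `x`, `y` in cm. A plain 4x2 matrix is taken to be in that
#'   row order.
#' @return 4x2 numeric matrix with rownames `fl`, `fr`, `rl`, `rr`.
#' @export
paw_quad <- function(quad) {
  m <- as.matrix(quad)
  if (!all(dim(m) == c(4L, 2L))) stop("paw_quad: expected 4 points x 2 coords")
  if (is.null(rownames(m))) rownames(m) <- .vc_paws
  if (!setequal(rownames(m), .vc_paws)) {
    stop("paw_quad: rows must be labeled fl, fr, rl, rr")
  }
  colnames(m) <- c("x", "y")
  if (any(!is.finite(m))) stop("paw_quad: non-finite coordinates")
  m[.vc_paws, , drop = FALSE]
}

#' Session support surface, baseline-normalized
#'
#' A session value is the mean shoelace area over its repeated landing
#' trials (nominally 10 per session); the reported value is the session
#' mean divided by the animal's pre-operative session mean, so the
#' baseline maps to exactly 1.
#'
#' @param trials list of paw quads ([paw_quad()]) for the session (>= 1).
#' @param preop_trials list of pre-operative paw quads.
#' @return ratio (dimensionless) with attribute `n_trials`.
#' @export
support_surface_series <- function(trials, preop_trials) {
  if (length(trials) == 0L) stop("support_surface_series: no trials")
  if (length(preop_trials) == 0L) {
    stop("support_surface_series: no pre-operative trials")
  }
  post <- mean(vapply(trials, support_surface, numeric(1L)))
  pre <- mean(vapply(preop_trials, support_surface, numeric(1L)))
  if (pre == 0) {
    stop("support_surface_series: zero pre-operative support surface")
  }
  structure(post / pre, n_trials = length(trials))
}

#' Membrane fluorescence intensity with background-derived threshold
#'
#' Quantifies per-cell plasma-membrane fluorescence. The background region
#' (an area devoid of stained structures) yields a threshold
#' `T = mean + 3 * sd` of its pixel values; the whole image is reduced by
#' `T` and negative values are discarded. Within each membrane region of
#' interest, the reported value is the mean of the retained pixels whose
#' value reaches at least 80% of the region's maximum (the top-20%-of-max
#' band), which restricts the average to the brightest, membrane-proper
#' pixels under one criterion for every image. Cells with no pixel above
#' threshold are flagged and excluded from the image mean with a warning.
#'
#' @param image [image_grid()] (single channel).
#' @param rois list with `background` (integer pixel indices or logical
#'   mask, >= 50 pixels) and `membranes` (list of pixel index vectors or
#'   masks, one per cell body); see [ring_rois()].
#' @return list with `per_cell` (numeric, `NA` for below-threshold cells),
#'   `mean` (over measurable cells), `threshold`.
#' @export
membrane_intensity <- function(image, rois) {
  img <- as.numeric(image)
  bg_ix <- .roi_indices(rois$background, image)
  if (length(bg_ix) < 50L) {
    stop("membrane_intensity: background region must cover >= 50 pixels")
  }
  mem <- rois$membranes
  if (is.null(mem) || length(mem) == 0L) {
    stop("membrane_intensity: no membrane regions supplied")
  }
  mem_ix <- lapply(mem, .roi_indices, image = image)
  if (any(vapply(mem_ix, function(ix) any(ix %in% bg_ix), logical(1L)))) {
    stop("membrane_intensity: membrane regions overlap the background region")
  }
  thr <- mean(img[bg_ix]) + 3 * sd(img[bg_ix])
  shifted <- img - thr
  per_cell <- vapply(mem_ix, function(ix) {
    vals <- shifted[ix]
    vals <- vals[vals > 0]
    if (length(vals) == 0L) return(NA_real_)
    band <- vals[vals >= 0.8 * max(vals)]
    mean(band)
  }, numeric(1L))
  if (anyNA(per_cell)) {
    warning("membrane_intensity: ", sum(is.na(per_cell)),
            " cell(s) entirely below threshold; excluded from the mean")
  }
  list(per_cell = per_cell,
       mean = if (all(is.na(per_cell))) NA_real_
              else mean(per_cell, na.rm = TRUE),
       threshold = thr)
}

.roi_indices <- function(roi, image) {
  if (is.logical(roi)) which(roi) else as.integer(roi)
}

#' Square counting frame
#'
#' The microscopic counting chamber delimiting the counting region. The
#' frame is parameterized, never hard-coded: `side` is derived from the
#' configured chamber area when a pixel size is known, or given directly
#' in pixels.
#'
#' @param x0,y0 lower-left corner (pixel coordinates, row = y, col = x).
#' @param side side length in pixels.
#' @return list of class `counting_frame`.
#' @export
counting_frame <- function(x0, y0, side) {
  stopifnot(side > 0)
  structure(list(x0 = x0, y0 = y0, side = side), class = "counting_frame")
}

#' Count labeled cells inside a counting frame
#'
#' A stand-in for manual counting, validated on synthetic images:
#' background subtraction, a fixed threshold (default: image mean + 3 sd),
#' connected-component labeling, a minimum blob area, and the rule that a
#' cell is counted when its centroid lies inside the frame.
#'
#' @param image [image_grid()] single channel.
#' @param frame [counting_frame()].
#' @param threshold intensity threshold; `NULL` uses mean + 3 sd of the
#'   image.
#' @param min_area minimum blob area in pixels.
#' @return integer count, with attribute `centroids` (matrix x, y of
#'   counted cells).
#' @export
count_cells <- function(image, frame, threshold = NULL, min_area = 5L) {
  img <- unclass(image)
  attributes(img) <- attributes(img)["dim"]
  if (is.null(threshold)) threshold <- mean(img) + 3 * sd(img)
  bw <- img > threshold
  lab <- EBImage::bwlabel(bw)
  n_lab <- max(lab)
  if (n_lab == 0L) {
    return(structure(0L, centroids = matrix(numeric(0), 0L, 2L,
                                            dimnames = list(NULL, c("x", "y")))))
  }
  ix <- which(lab > 0)
  labs <- lab[ix]
  rows <- (ix - 1L) %% nrow(img) + 1L
  cols <- (ix - 1L) %/% nrow(img) + 1L
  area <- tabulate(labs, n_lab)
  cy <- tapply(rows, labs, mean)  # row index = y
  cx <- tapply(cols, labs, mean)  # col index = x
  keep <- area >= min_area &
    cx >= frame$x0 & cx <= frame$x0 + frame$side &
    cy >= frame$y0 & cy <= frame$y0 + frame$side
  structure(as.integer(sum(keep)),
            centroids = cbind(x = as.numeric(cx[keep]),
                              y = as.numeric(cy[keep])))
}

#' Average per-section counts for one animal
#'
#' Cell counts are averaged over the serial sections of an animal
#' (nominally 10 +/- 2 sections).
#'
#' @param sections numeric vector of per-section counts (>= 1).
#' @return mean count.
#' @export
average_counts <- function(sections) {
  if (length(sections) == 0L) stop("average_counts: empty section list")
  if (any(sections < 0)) stop("average_counts: counts must be >= 0")
  mean(sections)
}

#' Percentage of marker-positive cells colocalized with nuclei
#'
#' Greedy one-to-one matching: marker/nuclear centroid pairs are matched
#' in order of increasing distance as long as the distance is within
#' `match_radius`; the result is the percent of marker cells matched.
#'
#' @param marker_cells,nuclear_cells two-column matrices (x, y) of
#'   centroids, same physical units as `match_radius`.
#' @param match_radius maximum centroid distance for a match (default
#'   3 um for nuclear colocalization).
#' @return percent, or `NA` when there are no marker cells.
#' @export
colocalization_pct <- function(marker_cells, nuclear_cells, match_radius = 3) {
  m <- as.matrix(marker_cells)
  n <- as.matrix(nuclear_cells)
  if (nrow(m) == 0L) {
    warning("colocalization_pct: no marker-positive cells; returning NA")
    return(NA_real_)
  }
  if (nrow(n) == 0L) return(0)
  d <- sqrt(outer(m[, 1L], n[, 1L], "-")^2 + outer(m[, 2L], n[, 2L], "-")^2)
  cand <- which(d <= match_radius, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(0)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_m <- logical(nrow(m)); used_n <- logical(nrow(n))
  matched <- 0L
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1L]; b <- cand[i, 2L]
    if (!used_m[a] && !used_n[b]) {
      used_m[a] <- TRUE; used_n[b] <- TRUE
      matched <- matched + 1L
    }
  }
  100 * matched / nrow(m)
}

#' Survival rate of proliferative cells
#'
#' Percent of cells marked during the acute phase that persist at the late
#' time point: `100 * mean_count_late / mean_count_acute`.
#'
#' @param mean_count_d3 mean count at the acute time point (> 0).
#' @param mean_count_d30 mean count at the late time point.
#' @return percent; values above 100 are allowed and flagged with a
#'   message.
#' @export
survival_rate <- function(mean_count_d3, mean_count_d30) {
  if (mean_count_d3 <= 0) {
    stop("survival_rate: acute-phase mean count must be > 0")
  }
  pct <- 100 * mean_count_d30 / mean_count_d3
  if (pct > 100) {
    message("survival_rate: rate exceeds 100% (late count above acute count)")
  }
  pct
}
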