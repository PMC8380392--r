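#' Construct and validate a videotracking trajectory
#'
#' Holds timestamped nose / body-center / tail-base coordinates (cm) in
#' the arena frame. Missing samples (tracking dropouts) are kept as `NA`
#' rows and treated as masked by downstream metrics, never dropped at
#' read time.
#'
#' @param df data.frame with columns `t`, `nose_x`, `nose_y`, `center_x`,
#'   `center_y`, `tail_x`, `tail_y`.
#' @param arena_size numeric length-2, arena width and depth in cm
#'   (default 80 x 80 open field).
#' @param bounds_tol tolerance (cm) allowed outside the arena before a
#'   warning is raised.
#' @return validated data.frame with class `trajectory` and an
#'   `arena_size` attribute.
#' @export
trajectory <- function(df, arena_size = c(80, 80), bounds_tol = 2) {
  cols <- c("t", "nose_x", "nose_y", "center_x", "center_y",
            "tail_x", "tail_y")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("trajectory: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[cols]
  if (nrow(df) < 2L) stop("trajectory: need at least 2 samples")
  if (anyNA(df$t) || any(diff(df$t) <= 0)) {
    stop("trajectory: timestamps must be strictly increasing and non-missing")
  }
  xy <- as.matrix(df[, -1L])
  lo <- -bounds_tol
  hi <- rep(c(arena_size[1], arena_size[2]), times = 3L) + bounds_tol
  out_of_bounds <- sweep(xy, 2L, hi, ">") | xy < lo
  if (any(out_of_bounds, na.rm = TRUE)) {
    warning("trajectory: ", sum(apply(out_of_bounds, 1L, any, na.rm = TRUE)),
            " sample(s) outside arena bounds (tolerance ", bounds_tol, " cm)")
  }
  attr(df, "arena_size") <- arena_size
  class(df) <- c("trajectory", "data.frame")
  df
}

#' Read a videotracking trajectory CSV
#'
#' Rows with missing coordinates are retained as masked samples.
#'
#' @param path CSV with columns `t`, `nose_x`, `nose_y`, `center_x`,
#'   `center_y`, `tail_x`, `tail_y`.
#' @param arena_size,bounds_tol passed to [trajectory()].
#' @return a validated [trajectory()].
#' @export
read_trajectory <- function(path, arena_size = c(80, 80), bounds_tol = 2) {
  df <- read.csv(path)
  trajectory(df, arena_size = arena_size, bounds_tol = bounds_tol)
}

#' Write a trajectory to CSV
#'
#' @param traj [trajectory()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
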