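#' Construct and validate a dynamic weight-bearing force-frame table
#'
#' A force-frame table holds one row per DWB sample: a timestamp, the
#' position (cm) and support force (g) of each paw (FL, FR, RL, RR), and
#' the abdomen force (g). Coordinates follow the package convention:
#' x antero-posterior (positive toward the head), y lateral (positive
#' toward the animal's right).
#'
#' @param df data.frame with columns `t`, `flx`, `fly`, `flw`, `frx`,
#'   `fry`, `frw`, `rlx`, `rly`, `rlw`, `rrx`, `rry`, `rrw`, `abdomen_w`.
#' @return the validated data.frame with class `force_frames`.
#' @export
force_frames <- function(df) {
  cols <- .vc_force_cols()
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("force_frames: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[cols]
  for (col in cols) {
    if (!is.numeric(df[[col]])) {
      stop("force_frames: column '", col, "' must be numeric")
    }
  }
  coord_cols <- as.vector(t(outer(.vc_paws, c("x", "y"), paste0)))
  bad_coord <- !complete.cases(df[coord_cols]) |
    !apply(df[coord_cols], 1L, function(z) all(is.finite(z)))
  if (any(bad_coord)) {
    stop("force_frames: non-finite paw coordinate(s) in row(s) ",
         paste(utils::head(which(bad_coord), 5L), collapse = ", "))
  }
  w_cols <- c(paste0(.vc_paws, "w"), "abdomen_w")
  for (col in w_cols) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0L) {
      stop("force_frames: negative or non-finite force in column '", col,
           "', row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  if (nrow(df) > 1L && any(diff(df$t) <= 0)) {
    stop("force_frames: timestamps must be strictly increasing (first ",
         "violation at row ", which(diff(df$t) <= 0)[1L] + 1L, ")")
  }
  class(df) <- c("force_frames", "data.frame")
  df
}

#' Default column dialect for DWB CSV exports
#'
#' DWB device exports name their columns differently across software
#' versions; readers therefore take a dialect, a named character vector
#' mapping canonical names (`t`, `flx`, ..., `abdomen_w`) to the column
#' headers found in the file. The default dialect uses the canonical names
#' in the conventional `FLx`/`FLw` capitalisation.
#'
#' @return named character vector (canonical name -> file column header).
#' @export
force_dialect <- function() {
  cols <- .vc_force_cols()
  pretty <- cols
  for (p in .vc_paws) {
    for (ax in c("x", "y", "w")) {
      pretty[pretty == paste0(p, ax)] <- paste0(toupper(p), ax)
    }
  }
  setNames(pretty, cols)
}

#' Read a DWB force-frame CSV
#'
#' @param path CSV file, one row per sample.
#' @param dialect named character vector mapping canonical column names to
#'   the headers used in the file; see [force_dialect()].
#' @return a validated [force_frames()] table.
#' @export
read_force_frames <- function(path, dialect = force_dialect()) {
  raw <- read.csv(path, check.names = FALSE)
  missing <- setdiff(unname(dialect), names(raw))
  if (length(missing) > 0L) {
    stop("read_force_frames: '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- raw[unname(dialect)]
  names(df) <- names(dialect)
  # +1 for the header line so reported numbers match the file
  tryCatch(force_frames(df), error = function(e) {
    stop("read_force_frames: ", path, ": ", conditionMessage(e),
         " (row numbers exclude the header line)", call. = FALSE)
  })
}

#' Write a force-frame table to CSV
#'
#' @param frames [force_frames()] table.
#' @param path output CSV path.
#' @param dialect column dialect, as in [read_force_frames()].
#' @return `path`, invisibly.
#' @export
write_force_frames <- function(frames, path, dialect = force_dialect()) {
  frames <- force_frames(frames)
  out <- as.data.frame(frames)[names(dialect)]
  names(out) <- unname(dialect)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
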