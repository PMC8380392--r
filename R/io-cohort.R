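#' Write a cohort to disk in the package's exchange layout
#'
#' Serializes a [simulate_cohort()] result (or a compatible list built
#' from real exports) as plain files that the package readers consume:
#' `records.csv`, `checklists.csv`, `quads.csv`, one force-frame CSV per
#' DWB recording under `dwb/`, one trajectory CSV per acquisition under
#' `trajectories/`, `cells.csv`, and 16-bit TIFFs under `images/`
#' (intensities rounded to integer grey levels).
#'
#' @param cohort a `vc_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$records, file.path(dir, "records.csv"),
            row.names = FALSE)
  if (!is.null(cohort$checklists)) {
    write.csv(cohort$checklists, file.path(dir, "checklists.csv"),
              row.names = FALSE)
  }
  if (!is.null(cohort$quads)) {
    rows <- list()
    for (key in names(cohort$quads)) {
      for (i in seq_along(cohort$quads[[key]])) {
        q <- cohort$quads[[key]][[i]]
        rows[[length(rows) + 1L]] <- data.frame(
          record = key, trial = i,
          flx = q["fl", "x"], fly = q["fl", "y"],
          frx = q["fr", "x"], fry = q["fr", "y"],
          rlx = q["rl", "x"], rly = q["rl", "y"],
          rrx = q["rr", "x"], rry = q["rr", "y"])
      }
    }
    write.csv(do.call(rbind, rows), file.path(dir, "quads.csv"),
              row.names = FALSE)
  }
  if (!is.null(cohort$dwb)) {
    dir.create(file.path(dir, "dwb"), showWarnings = FALSE)
    for (key in names(cohort$dwb)) {
      write_force_frames(cohort$dwb[[key]],
                         file.path(dir, "dwb", paste0(key, ".csv")))
    }
  }
  if (!is.null(cohort$trajectories)) {
    dir.create(file.path(dir, "trajectories"), showWarnings = FALSE)
    for (key in names(cohort$trajectories)) {
      write_trajectory(cohort$trajectories[[key]],
                       file.path(dir, "trajectories", paste0(key, ".csv")))
    }
  }
  if (!is.null(cohort$cells)) {
    write.csv(cohort$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  }
  if (!is.null(cohort$images)) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    for (kind in names(cohort$images)) {
      for (id in names(cohort$images[[kind]])) {
        img <- round(unclass(cohort$images[[kind]][[id]]$image))
        img[img > 65535] <- 65535
        write_image(image_grid(img),
                    file.path(dir, "images",
                              paste0(kind, "_", id, ".tif")), bits = 16L)
      }
    }
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Rebuilds the in-memory cohort list (records, checklists, quads, DWB
#' force frames, trajectories, cell counts) from the on-disk layout; all
#' tables are re-validated on the way in. Images are listed but loaded
#' lazily by the caller via [read_image()].
#'
#' @param dir cohort directory.
#' @return a `vc_cohort`-shaped list.
#' @export
read_cohort <- function(dir) {
  out <- list(records = read.csv(file.path(dir, "records.csv")))
  cl_path <- file.path(dir, "checklists.csv")
  if (file.exists(cl_path)) out$checklists <- read.csv(cl_path)
  quad_path <- file.path(dir, "quads.csv")
  if (file.exists(quad_path)) {
    qd <- read.csv(quad_path)
    out$quads <- lapply(split(qd, qd$record), function(d) {
      d <- d[order(d$trial), ]
      lapply(seq_len(nrow(d)), function(i) {
        paw_quad(rbind(fl = c(d$flx[i], d$fly[i]),
                       fr = c(d$frx[i], d$fry[i]),
                       rl = c(d$rlx[i], d$rly[i]),
                       rr = c(d$rrx[i], d$rry[i])))
      })
    })
  }
  dwb_dir <- file.path(dir, "dwb")
  if (dir.exists(dwb_dir)) {
    files <- list.files(dwb_dir, pattern = "\\.csv$")
    out$dwb <- setNames(
      lapply(files, function(f) read_force_frames(file.path(dwb_dir, f))),
      sub("\\.csv$", "", files))
  }
  traj_dir <- file.path(dir, "trajectories")
  if (dir.exists(traj_dir)) {
    files <- list.files(traj_dir, pattern = "\\.csv$")
    out$trajectories <- setNames(
      lapply(files, function(f) read_trajectory(file.path(traj_dir, f))),
      sub("\\.csv$", "", files))
  }
  cells_path <- file.path(dir, "cells.csv")
  if (file.exists(cells_path)) out$cells <- read.csv(cells_path)
  img_dir <- file.path(dir, "images")
  if (dir.exists(img_dir)) {
    out$image_files <- list.files(img_dir, full.names = TRUE)
  }
  class(out) <- "vc_cohort"
  out
}
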