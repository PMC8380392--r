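#' Analysis configuration defaults
#'
#' One nested list holding every tunable threshold of the quantification
#' chain, so that a run is fully described by (config, inputs, seed).
#' All values are conventions of this package, documented in the methods
#' vignette, and can be overridden per call or via a YAML file.
#'
#' @param ... named overrides merged over the defaults with
#'   [utils::modifyList()]; nested lists merge recursively.
#' @return nested list with components `stance` (min_paw_force g,
#'   min_duration s, max_barycenter_speed cm/s), `circling` (min_speed
#'   cm/s), `kinematics` (smoothing_window s), `images` (colocalization
#'   match radius um, counting-frame area, min blob area px), `anova`
#'   (tukey family mode).
#' @export
vc_config <- function(...) {
  cfg <- list(
    stance = list(
      min_paw_force = 5,        # g; paw considered loaded
      min_duration = 0.2,       # s; shortest stance epoch retained
      max_barycenter_speed = 2  # cm/s; static criterion within an epoch
    ),
    circling = list(min_speed = 5),   # cm/s; "fast" lap gate
    kinematics = list(smoothing_window = 0.5),  # s boxcar before differencing
    images = list(
      match_radius = 3,          # um; colocalization centroid matching
      counting_frame_area = 425.10,  # reported counting-chamber area
      min_blob_area = 5          # px; connected-component size floor
    ),
    anova = list(family = "cells")  # Tukey family: all group x time cells
  )
  dots <- list(...)
  if (length(dots) > 0L) cfg <- modifyList(cfg, dots)
  cfg
}

#' Read or write a configuration as YAML
#'
#' @param path YAML file.
#' @return `read_config()` returns the merged configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  do.call(vc_config, yaml::read_yaml(path))
}

#' @param cfg configuration list.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
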