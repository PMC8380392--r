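#' Quantify every record of a cohort into a tidy metrics table
#'
#' Runs the full measurement chain on whichever components the cohort
#' carries: syndrome score from checklists, support-surface ratio from
#' landing quads, posturographic metrics from DWB streams (laterality
#' index, rearing fraction and, against the animal's preop recording,
#' abdomen load, mean lateral barycenter position, barycenter inertia and
#' maximum lateral deviation ratios), and open-field kinematics from
#' trajectories (distance/velocity/acceleration ratios, torsion
#' difference, left circling count). Post-operative records without a
#' preop baseline yield missing normalized values, never imputed.
#'
#' @param cohort a `vc_cohort` from [simulate_cohort()] (or a list of the
#'   same shape assembled from disk).
#' @param config analysis configuration, see [vc_config()].
#' @return tidy data.frame: `animal_id`, `group`, `timepoint`, `day`,
#'   `metric`, `value`, `units`, `normalization`.
#' @export
quantify_cohort <- function(cohort, config = vc_config()) {
  rec <- cohort$records
  key <- paste(rec$animal_id, rec$timepoint, sep = ".")
  preop_key <- setNames(paste(rec$animal_id, "preop", sep = "."),
                        key)
  rows <- list()
  emit <- function(i, metric, value, units, normalization) {
    rows[[length(rows) + 1L]] <<- data.frame(
      animal_id = rec$animal_id[i], group = rec$group[i],
      timepoint = rec$timepoint[i], day = rec$day[i],
      metric = metric, value = as.numeric(value), units = units,
      normalization = normalization)
  }

  if (!is.null(cohort$checklists)) {
    sc <- syndrome_score(cohort$checklists)
    for (i in seq_len(nrow(rec))) {
      emit(i, "syndrome_score", sc[i], "score", "none")
    }
  }

  if (!is.null(cohort$quads)) {
    for (i in seq_len(nrow(rec))) {
      if (rec$day[i] == 0) next
      pre <- cohort$quads[[preop_key[[key[i]]]]]
      if (is.null(pre)) next
      emit(i, "support_surface",
           support_surface_series(cohort$quads[[key[i]]], pre),
           "ratio", "ratio_to_preop")
    }
  }

  if (!is.null(cohort$dwb)) {
    st <- config$stance
    sks <- lapply(key, function(k) {
      fr <- cohort$dwb[[k]]
      if (is.null(fr)) return(NULL)
      ep <- detect_stance_epochs(fr, st$min_paw_force, st$min_duration,
                                 st$max_barycenter_speed)
      if (nrow(ep) == 0L) return(NULL)
      build_statokinesigram(ep)
    })
    names(sks) <- key
    for (i in seq_len(nrow(rec))) {
      fr <- cohort$dwb[[key[i]]]
      if (is.null(fr)) next
      emit(i, "laterality_index", laterality_index(fr), "g", "none")
      emit(i, "rearing_fraction",
           rearing_fraction(fr, st$min_paw_force), "percent", "none")
      if (rec$day[i] == 0) next
      pre_fr <- cohort$dwb[[preop_key[[key[i]]]]]
      if (is.null(pre_fr)) next
      emit(i, "abdomen_load", abdomen_load(fr, pre_fr), "g",
           "diff_from_preop")
      sk <- sks[[key[i]]]; pre_sk <- sks[[preop_key[[key[i]]]]]
      if (is.null(sk) || is.null(pre_sk)) next
      emit(i, "lateral_position", mean_lateral_position(sk, pre_sk),
           "cm", "diff_from_preop")
      # a degenerate (single-epoch) preop baseline leaves the ratio missing
      emit(i, "barycenter_inertia",
           tryCatch(barycenter_inertia(sk, pre_sk),
                    error = function(e) NA_real_),
           "ratio", "ratio_to_preop")
      emit(i, "max_lateral_deviation",
           tryCatch(max_lateral_deviation(sk, pre_sk),
                    error = function(e) NA_real_),
           "ratio", "ratio_to_preop")
    }
  }

  if (!is.null(cohort$trajectories)) {
    for (i in seq_len(nrow(rec))) {
      traj <- cohort$trajectories[[key[i]]]
      if (is.null(traj)) next
      emit(i, "left_circling",
           circling_count(traj, config$circling$min_speed, "left"),
           "laps", "none")
      if (rec$day[i] == 0) next
      pre <- cohort$trajectories[[preop_key[[key[i]]]]]
      if (is.null(pre)) next
      km_post <- path_metrics(traj, config$kinematics$smoothing_window)
      km_pre <- path_metrics(pre, config$kinematics$smoothing_window)
      km_post$mean_body_torsion <- suppressWarnings(body_torsion(traj))
      km_pre$mean_body_torsion <- suppressWarnings(body_torsion(pre))
      nk <- normalize_kinematics(km_post, km_pre)
      emit(i, "total_distance", nk$total_distance, "ratio",
           "ratio_to_preop")
      emit(i, "mean_velocity", nk$mean_velocity, "ratio", "ratio_to_preop")
      emit(i, "mean_acceleration", nk$mean_acceleration, "ratio",
           "ratio_to_preop")
      emit(i, "mean_body_torsion", nk$mean_body_torsion, "deg",
           "diff_from_preop")
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates (or accepts) a cohort, quantifies it into a tidy metrics
#' table, runs the split-plot ANOVA and placebo-vs-treated Tukey
#' comparisons for each behavioral metric, and writes the results plus a
#' reproducibility manifest into `out_dir`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param components data components to simulate, see [simulate_cohort()].
#' @param cohort optional pre-built `vc_cohort` (then `config` is only
#'   recorded); useful to analyze data read from disk.
#' @param analysis_config a [vc_config()].
#' @return invisibly, a list with `metrics` (tidy table), `comparisons`,
#'   `anova` (per-metric fits) and the output paths.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         components = c("checklists", "quads",
                                        "trajectories"),
                         cohort = NULL, analysis_config = vc_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    vc_log("simulating cohort (seed ", config$seed, ")")
    cohort <- simulate_cohort(config, components = components)
  }
  vc_log("quantifying ", nrow(cohort$records), " records")
  metrics <- quantify_cohort(cohort, analysis_config)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  lesioned <- names(config$groups)[vapply(config$groups, `[[`, logical(1L),
                                          "lesioned")]
  pair <- if (length(lesioned) >= 2L) lesioned[1:2] else NULL
  fits <- list()
  comps <- list()
  for (m in unique(metrics$metric)) {
    sub <- metrics[metrics$metric == m & is.finite(metrics$value), ]
    tab <- data.frame(animal_id = sub$animal_id, group = sub$group,
                      timepoint = sub$timepoint, value = sub$value)
    fit <- tryCatch(
      suppressWarnings(vc_anova(tab, repeated = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits[[m]] <- fit
    if (!is.null(pair) && all(pair %in% levels(fit$cells$group))) {
      rep_m <- tryCatch(tukey_report(fit, group_pair = pair),
                        error = function(e) NULL)
      if (!is.null(rep_m)) {
        rep_m <- cbind(analysis = m, rep_m)
        comps[[m]] <- rep_m
      }
    }
  }
  comparisons <- if (length(comps) > 0L) do.call(rbind, comps) else NULL
  if (!is.null(comparisons)) {
    rownames(comparisons) <- NULL
    write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
              row.names = FALSE)
  }

  if (!is.null(cohort$dwb) && length(cohort$dwb) > 0L) {
    st <- analysis_config$stance
    fr <- cohort$dwb[[1L]]
    ep <- detect_stance_epochs(fr, st$min_paw_force, st$min_duration,
                               st$max_barycenter_speed)
    if (nrow(ep) > 0L) {
      sk <- build_statokinesigram(ep)
      write.csv(sk$points, file.path(out_dir, "statokinesigram.csv"),
                row.names = FALSE)
      grDevices::png(file.path(out_dir, "statokinesigram.png"),
                     width = 600, height = 600)
      plot(sk, main = names(cohort$dwb)[1L])
      dev.off()
    }
  }

  manifest <- list(
    package = "vestcomp",
    version = as.character(utils::packageVersion("vestcomp")),
    seed = config$seed,
    components = intersect(c("checklists", "quads", "dwb", "trajectories",
                             "cells", "images"), names(cohort)),
    n_records = nrow(cohort$records),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  vc_log("pipeline outputs written to ", out_dir)
  invisible(list(metrics = metrics, comparisons = comparisons,
                 anova = fits, out_dir = out_dir))
}
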