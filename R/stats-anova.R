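#' Two-way ANOVA for group x time designs
#'
#' Fits either an ordinary two-factor ANOVA (independent design, e.g.
#' cellular markers where different animals are sacrificed at each time
#' point) or a split-plot / mixed ANOVA for the 1-between ("group"),
#' 1-within ("time") repeated-measures design used for behavioral time
#' courses. In the repeated design the group effect is tested against the
#' between-subject error and time and group x time against the
#' within-subject error; no sphericity correction is applied by default.
#'
#' @param data data.frame with columns `animal_id`, `group`, `timepoint`,
#'   `value` (one value per animal x timepoint).
#' @param repeated logical; `TRUE` for the split-plot repeated-measures
#'   design. Animals with incomplete within-subject series are dropped
#'   with a warning.
#' @return object of class `vc_anova`: list with `effects` (data.frame
#'   of F, df pairs and p for group, time, group:time), `cells` (cell
#'   means and sizes), `error` (error mean squares and df per stratum),
#'   `repeated`, `n_animals`.
#' @export
vc_anova <- function(data, repeated = FALSE) {
  need <- c("animal_id", "group", "timepoint", "value")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L) {
    stop("vc_anova: missing column(s): ", paste(missing, collapse = ", "))
  }
  data <- data[complete.cases(data[need]), need]
  data$group <- factor(data$group, levels = unique(data$group))
  # keep acquisition order (d1, d2, ..., d30), not alphabetical order
  data$timepoint <- factor(data$timepoint, levels = unique(data$timepoint))
  data$animal_id <- factor(data$animal_id)
  if (nlevels(data$group) < 2L || nlevels(data$timepoint) < 2L) {
    stop("vc_anova: need at least 2 groups and 2 timepoints")
  }
  if (anyDuplicated(data[c("animal_id", "timepoint")])) {
    stop("vc_anova: more than one value per animal x timepoint")
  }

  if (repeated) {
    n_tp <- nlevels(data$timepoint)
    per_animal <- table(data$animal_id)
    incomplete <- names(per_animal)[per_animal < n_tp]
    if (length(incomplete) > 0L) {
      warning("vc_anova: dropping ", length(incomplete),
              " animal(s) with incomplete within-subject series")
      data <- data[!data$animal_id %in% incomplete, ]
      data$animal_id <- droplevels(data$animal_id)
      data$group <- droplevels(data$group)
      if (nlevels(data$group) < 2L) {
        stop("vc_anova: fewer than 2 groups after dropping incomplete animals")
      }
    }
    fit <- aov(value ~ group * timepoint + Error(animal_id), data = data)
    sm <- summary(fit)
    btw <- sm[["Error: animal_id"]][[1L]]
    wth <- sm[["Error: Within"]][[1L]]
    rn_b <- trimws(rownames(btw)); rn_w <- trimws(rownames(wth))
    g <- which(rn_b == "group"); rb <- which(rn_b == "Residuals")
    ti <- which(rn_w == "timepoint"); gt <- which(rn_w == "group:timepoint")
    rw <- which(rn_w == "Residuals")
    effects <- data.frame(
      effect = c("group", "time", "group:time"),
      df1 = c(btw$Df[g], wth$Df[ti], wth$Df[gt]),
      df2 = c(btw$Df[rb], wth$Df[rw], wth$Df[rw]),
      F = c(btw$`F value`[g], wth$`F value`[ti], wth$`F value`[gt]),
      p = c(btw$`Pr(>F)`[g], wth$`Pr(>F)`[ti], wth$`Pr(>F)`[gt]))
    error <- list(between = list(ms = btw$`Mean Sq`[rb], df = btw$Df[rb]),
                  within = list(ms = wth$`Mean Sq`[rw], df = wth$Df[rw]))
  } else {
    fit <- aov(value ~ group * timepoint, data = data)
    sm <- summary(fit)[[1L]]
    rn <- trimws(rownames(sm))
    g <- which(rn == "group"); ti <- which(rn == "timepoint")
    gt <- which(rn == "group:timepoint"); rs <- which(rn == "Residuals")
    effects <- data.frame(
      effect = c("group", "time", "group:time"),
      df1 = sm$Df[c(g, ti, gt)],
      df2 = rep(sm$Df[rs], 3L),
      F = sm$`F value`[c(g, ti, gt)],
      p = sm$`Pr(>F)`[c(g, ti, gt)])
    error <- list(residual = list(ms = sm$`Mean Sq`[rs], df = sm$Df[rs]))
  }

  cells <- aggregate(value ~ group + timepoint, data = data,
                     FUN = function(z) c(mean = mean(z), n = length(z)))
  cells <- data.frame(group = cells$group, timepoint = cells$timepoint,
                      mean = cells$value[, "mean"],
                      n = as.integer(cells$value[, "n"]))

  structure(list(effects = effects, cells = cells, error = error,
                 repeated = repeated,
                 n_animals = nlevels(data$animal_id),
                 n_timepoints = nlevels(data$timepoint)),
            class = "vc_anova")
}

#' @export
print.vc_anova <- function(x, ...) {
  cat(if (x$repeated) "Split-plot (1-between, 1-within) two-way ANOVA\n"
      else "Independent two-way ANOVA\n")
  eff <- x$effects
  eff$F <- signif(eff$F, 4L)
  eff$p <- format.pval(eff$p, digits = 3L)
  print(eff, row.names = FALSE)
  invisible(x)
}

#' @export
summary.vc_anova <- function(object, ...) {
  print(object)
  cat("\nCell means:\n")
  print(object$cells, row.names = FALSE)
  invisible(object)
}

#' @importFrom stats aggregate
NULL
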