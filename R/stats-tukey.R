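#' Upper-tail p of the studentized range
#'
#' Probability that the studentized range of `k` means exceeds `q`, with
#' `df` error degrees of freedom -- the reference distribution for Tukey
#' multiple comparisons, evaluated by numerical integration.
#'
#' @param q studentized-range statistic (>= 0).
#' @param k number of means in the family (>= 2).
#' @param df error degrees of freedom (>= 1).
#' @return upper-tail probability; strictly decreasing in `q`,
#'   `p(0) = 1`.
#' @export
studentized_range_p <- function(q, k, df) {
  if (any(k < 2)) stop("studentized_range_p: k must be >= 2")
  if (any(df < 1)) stop("studentized_range_p: df must be >= 1")
  if (any(q < 0)) stop("studentized_range_p: q must be >= 0")
  ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
}

.p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Tukey pairwise comparisons from cell means and an error mean square
#'
#' For each requested pair of cells the standard error of the difference
#' is the (Tukey-Kramer) `sqrt(MSE * (1/n1 + 1/n2))`, the studentized-
#' range ratio is `q = sqrt(2) * |mean_1 - mean_2| / se_diff`, and the
#' adjusted p-value comes from the studentized-range distribution with
#' family size `k` and `df` error degrees of freedom.
#'
#' @param means named numeric vector of cell means.
#' @param ns cell sizes (single number or vector matching `means`).
#' @param mse error mean square.
#' @param df error degrees of freedom (> 0).
#' @param k family size (number of means the correction spans); defaults
#'   to `length(means)`.
#' @param pairs two-column matrix of cell names (or indices) to compare;
#'   default: all pairs.
#' @return data.frame of class `tukey_comparisons` with columns
#'   `comparison`, `mean_1`, `mean_2`, `se_diff`, `q`, `df`, `p`, `stars`.
#' @export
tukey_pairs <- function(means, ns, mse, df, k = length(means), pairs = NULL) {
  if (df <= 0) stop("tukey_pairs: error df must be > 0")
  if (length(ns) == 1L) ns <- rep(ns, length(means))
  if (is.null(names(means))) names(means) <- seq_along(means)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(names(means), 2L))
  }
  pairs <- cbind(as.character(pairs[, 1L]), as.character(pairs[, 2L]))
  m1 <- means[pairs[, 1L]]; m2 <- means[pairs[, 2L]]
  n1 <- ns[match(pairs[, 1L], names(means))]
  n2 <- ns[match(pairs[, 2L], names(means))]
  se <- sqrt(mse * (1 / n1 + 1 / n2))
  q <- sqrt(2) * abs(m1 - m2) / se
  p <- studentized_range_p(q, k = k, df = df)
  out <- data.frame(comparison = paste(pairs[, 1L], "vs", pairs[, 2L]),
                    mean_1 = unname(m1), mean_2 = unname(m2),
                    se_diff = unname(se), q = unname(q), df = df,
                    p = unname(p), stars = .p_stars(unname(p)))
  class(out) <- c("tukey_comparisons", "data.frame")
  out
}

#' Tukey q ratio and p from printed means and SE of difference
#'
#' Recomputes studentized-range ratios the way they are reported in
#' comparison tables: from two cell means, the standard error of their
#' difference, and the error degrees of freedom,
#' `q = sqrt(2) * |mean_1 - mean_2| / se_diff`. Useful both for worked
#' examples and for checking published tables.
#'
#' @param mean_1,mean_2 cell means (vectorized).
#' @param se_diff standard error of the difference between the two means.
#' @param df error degrees of freedom.
#' @param k family size for the Tukey adjustment (default 3, the
#'   three-group family).
#' @param label optional row labels.
#' @return `tukey_comparisons` data.frame (see [tukey_pairs()]).
#' @export
tukey_from_means <- function(mean_1, mean_2, se_diff, df, k = 3L,
                             label = NULL) {
  stopifnot(length(mean_2) == length(mean_1),
            all(se_diff > 0), all(df > 0))
  q <- sqrt(2) * abs(mean_1 - mean_2) / se_diff
  p <- studentized_range_p(q, k = k, df = df)
  out <- data.frame(
    comparison = label %||% paste0("pair_", seq_along(mean_1)),
    mean_1 = mean_1, mean_2 = mean_2, se_diff = se_diff,
    q = q, df = df, p = p, stars = .p_stars(p))
  class(out) <- c("tukey_comparisons", "data.frame")
  out
}

#' @export
print.tukey_comparisons <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("mean_1", "mean_2", "se_diff", "q")) {
    y[[col]] <- signif(y[[col]], 4L)
  }
  y$p <- format.pval(y$p, digits = 3L)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Table-style Tukey report for a fitted group x time ANOVA
#'
#' Builds the comparison rows conventional in this literature: one row per
#' requested group pair at each time point, with cell means, SE of the
#' difference, the q ratio, error df and the Tukey-adjusted p. The family
#' spans all group x time cell means by default.
#'
#' For the independent design the error term is the residual mean square.
#' For the split-plot design, comparisons of groups at a fixed time pool
#' the between- and within-subject errors,
#' `(MS_between + (T - 1) MS_within) / T`, with Satterthwaite degrees of
#' freedom.
#'
#' @param fit a [vc_anova()] object.
#' @param group_pair length-2 character vector naming the two groups to
#'   compare (default: the last two group levels present).
#' @param family `"cells"` (family = all group x time cells) or
#'   `"groups"` (family = number of groups).
#' @return `tukey_comparisons` data.frame with a `delay` column.
#' @export
tukey_report <- function(fit, group_pair = NULL, family = c("cells", "groups")) {
  stopifnot(inherits(fit, "vc_anova"))
  family <- match.arg(family)
  cells <- fit$cells
  groups <- levels(cells$group)
  if (is.null(group_pair)) group_pair <- utils::tail(groups, 2L)
  stopifnot(length(group_pair) == 2L, all(group_pair %in% groups))
  tps <- levels(cells$timepoint)
  k <- if (family == "cells") nrow(cells) else length(groups)

  if (fit$repeated) {
    tnum <- fit$n_timepoints
    msb <- fit$error$between$ms; dfb <- fit$error$between$df
    msw <- fit$error$within$ms; dfw <- fit$error$within$df
    mse <- (msb + (tnum - 1) * msw) / tnum
    df <- (msb + (tnum - 1) * msw)^2 /
      (msb^2 / dfb + ((tnum - 1) * msw)^2 / dfw)
  } else {
    mse <- fit$error$residual$ms
    df <- fit$error$residual$df
  }

  rows <- lapply(tps, function(tp) {
    c1 <- cells[cells$group == group_pair[1L] & cells$timepoint == tp, ]
    c2 <- cells[cells$group == group_pair[2L] & cells$timepoint == tp, ]
    if (nrow(c1) == 0L || nrow(c2) == 0L) return(NULL)
    se <- sqrt(mse * (1 / c1$n + 1 / c2$n))
    q <- sqrt(2) * abs(c1$mean - c2$mean) / se
    p <- studentized_range_p(q, k = k, df = df)
    data.frame(delay = tp,
               comparison = paste(group_pair, collapse = " vs "),
               mean_1 = c1$mean, mean_2 = c2$mean, se_diff = se,
               q = q, df = df, p = p, stars = .p_stars(p))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  rownames(out) <- NULL
  class(out) <- c("tukey_comparisons", "data.frame")
  out
}
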