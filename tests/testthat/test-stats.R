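test_that("D'Agostino-Pearson K2 matches independently computed values", {
  # expected values computed with an independent implementation of the
  # omnibus test (moment-based, frozen)
  set.seed(42)
  x <- round(rnorm(60, 10, 2), 6)
  ht <- dagostino_pearson(x)
  expect_equal(unname(ht$statistic), 2.95642940740563, tolerance = 1e-10)
  expect_equal(ht$p.value, 0.2280444520948184, tolerance = 1e-10)
  expect_equal(ht$z_skew, -1.6010695630447611, tolerance = 1e-10)
  expect_equal(ht$z_kurt, 0.6269016363810893, tolerance = 1e-10)

  set.seed(7)
  y <- round(rlnorm(40), 6)
  ht2 <- dagostino_pearson(y)
  expect_equal(unname(ht2$statistic), 36.62016624105331, tolerance = 1e-8)
  expect_equal(ht2$p.value, 1.1169453837645544e-08, tolerance = 1e-6)

  expect_error(dagostino_pearson(rnorm(7)), "at least 8")
  expect_error(dagostino_pearson(rep(1, 20)), "constant")
  # QQ coordinates cover the sample
  expect_equal(nrow(ht$qq), 60)
  expect_equal(ht$qq$sample, sort(scale(x)[, 1]))
})

test_that("normality screen is calibrated and detects log-normal data", {
  set.seed(123)
  p_norm <- replicate(400, dagostino_pearson(rnorm(200))$p.value)
  rate <- mean(p_norm < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
  p_lnorm <- replicate(100, dagostino_pearson(rlnorm(200))$p.value)
  expect_gt(mean(p_lnorm < 0.05), 0.95)
})

test_that("independent two-way ANOVA matches a sums-of-squares oracle", {
  set.seed(55)
  mu <- rbind(g1 = c(d3 = 1, d30 = 2), g2 = c(d3 = 1.5, d30 = 1),
              g3 = c(d3 = 0, d30 = 3))
  tab <- make_table(mu, n_per_cell = 6, sd = 1.2)
  fit <- vc_anova(tab, repeated = FALSE)

  # oracle: textbook balanced two-factor sums of squares
  y <- tab$value
  g <- factor(tab$group); tp <- factor(tab$timepoint)
  grand <- mean(y)
  ss_a <- sum(tapply(y, g, function(z) length(z) * (mean(z) - grand)^2))
  ss_b <- sum(tapply(y, tp, function(z) length(z) * (mean(z) - grand)^2))
  cell <- tapply(y, list(g, tp), mean)
  ncell <- tapply(y, list(g, tp), length)
  ss_cells <- sum(ncell * (cell - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cells
  df_a <- nlevels(g) - 1; df_b <- nlevels(tp) - 1
  df_ab <- df_a * df_b; df_err <- length(y) - nlevels(g) * nlevels(tp)
  f_oracle <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab) / (ss_err / df_err)

  expect_equal(fit$effects$F, f_oracle, tolerance = 1e-10)
  expect_equal(fit$effects$df1, c(df_a, df_b, df_ab))
  expect_equal(fit$effects$df2, rep(df_err, 3))
  expect_equal(fit$effects$p,
               pf(f_oracle, c(df_a, df_b, df_ab), df_err, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(fit$error$residual$ms, ss_err / df_err, tolerance = 1e-10)

  # balanced decomposition: SS_total = SS_group + SS_time + SS_int + SS_err
  expect_equal(ss_tot, ss_a + ss_b + ss_ab + ss_err, tolerance = 1e-9)
})

test_that("split-plot ANOVA matches a hand-computed decomposition", {
  set.seed(56)
  mu <- rbind(g1 = c(t1 = 0, t2 = 1, t3 = 2), g2 = c(t1 = 1, t2 = 1, t3 = 1))
  tab <- make_table(mu, n_per_cell = 5, sd = 0.8, subject_effect = 0.7)
  fit <- vc_anova(tab, repeated = TRUE)

  y <- tab$value
  g <- factor(tab$group); tp <- factor(tab$timepoint)
  subj <- factor(tab$animal_id)
  G <- nlevels(g); Tn <- nlevels(tp); n <- nlevels(subj) / G
  grand <- mean(y)
  ss_subj <- Tn * sum((tapply(y, subj, mean) - grand)^2)
  ss_group <- n * Tn * sum((tapply(y, g, mean) - grand)^2)
  ss_berr <- ss_subj - ss_group
  ss_time <- n * G * sum((tapply(y, tp, mean) - grand)^2)
  cell <- tapply(y, list(g, tp), mean)
  ss_cells <- n * sum((cell - grand)^2)
  ss_int <- ss_cells - ss_group - ss_time
  ss_tot <- sum((y - grand)^2)
  ss_werr <- ss_tot - ss_subj - ss_time - ss_int
  df_berr <- G * (n - 1); df_werr <- (Tn - 1) * G * (n - 1)
  f_group <- (ss_group / (G - 1)) / (ss_berr / df_berr)
  f_time <- (ss_time / (Tn - 1)) / (ss_werr / df_werr)
  f_int <- (ss_int / ((G - 1) * (Tn - 1))) / (ss_werr / df_werr)

  expect_equal(fit$effects$F, c(f_group, f_time, f_int), tolerance = 1e-10)
  expect_equal(fit$effects$df2, c(df_berr, df_werr, df_werr))
  expect_equal(fit$error$between$ms, ss_berr / df_berr, tolerance = 1e-10)
  expect_equal(fit$error$within$ms, ss_werr / df_werr, tolerance = 1e-10)
})

test_that("repeated design drops incomplete animals with a warning", {
  set.seed(57)
  mu <- rbind(g1 = c(t1 = 0, t2 = 0), g2 = c(t1 = 0, t2 = 0))
  tab <- make_table(mu, n_per_cell = 6, sd = 1)
  tab <- tab[!(tab$animal_id == "s001" & tab$timepoint == "t2"), ]
  expect_warning(fit <- vc_anova(tab, repeated = TRUE), "incomplete")
  expect_equal(fit$n_animals, 11L)
  expect_error(vc_anova(tab[tab$group == "g1", ]), "2 groups")
})

test_that("Tukey pairs agree with TukeyHSD as an independent cross-check", {
  set.seed(58)
  k <- 4
  dat <- data.frame(cell = factor(rep(paste0("c", 1:k), each = 7)),
                    value = rnorm(7 * k) + rep(c(0, 0.5, 1, 0), each = 7))
  fit <- aov(value ~ cell, data = dat)
  hsd <- TukeyHSD(fit)$cell
  means <- tapply(dat$value, dat$cell, mean)
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  dfe <- summary(fit)[[1]]["Residuals", "Df"]
  ours <- tukey_pairs(means, ns = 7, mse = mse, df = dfe, k = k)
  # rows of TukeyHSD come in the same combn order
  expect_equal(ours$p, unname(hsd[, "p adj"]), tolerance = 1e-8)
  expect_equal(abs(hsd[, "diff"]),
               abs(ours$mean_1 - ours$mean_2), ignore_attr = TRUE)
})

test_that("studentized-range p behaves as a distribution function", {
  expect_equal(studentized_range_p(0, 3, 10), 1)
  q <- seq(0.5, 6, by = 0.5)
  p <- studentized_range_p(q, 3, 10)
  expect_true(all(diff(p) < 0))
  expect_error(studentized_range_p(1, 1, 10), "k must be")
  expect_error(studentized_range_p(1, 3, 0.5), "df must be")
  # equal means give q = 0 and p = 1
  tp <- tukey_pairs(c(a = 1, b = 1), ns = 5, mse = 2, df = 10)
  expect_equal(tp$q, 0)
  expect_equal(tp$p, 1)
})

test_that("tukey_from_means reproduces the q ratio convention", {
  row <- tukey_from_means(46.8, 8.33, 5.86, df = 67)
  expect_equal(row$q, sqrt(2) * abs(46.8 - 8.33) / 5.86)
  # q does not depend on the family size, p does
  r3 <- tukey_from_means(5, 3, 1, df = 20, k = 3)
  r6 <- tukey_from_means(5, 3, 1, df = 20, k = 6)
  expect_equal(r3$q, r6$q)
  expect_lt(r3$p, r6$p)
  expect_error(tukey_from_means(1, 2, 0, df = 10), "se_diff > 0")
})

test_that("tukey_report emits comparison rows per timepoint", {
  set.seed(59)
  mu <- rbind(sham = c(d3 = 0, d30 = 0), placebo = c(d3 = 2, d30 = 1),
              met = c(d3 = 4, d30 = 3))
  tab <- make_table(mu, n_per_cell = 8, sd = 1, subject_effect = 0.5)
  fit <- vc_anova(tab, repeated = TRUE)
  rep_tab <- tukey_report(fit, group_pair = c("placebo", "met"))
  expect_equal(nrow(rep_tab), 2L)
  expect_named(rep_tab, c("delay", "comparison", "mean_1", "mean_2",
                          "se_diff", "q", "df", "p", "stars"))
  expect_true(all(rep_tab$q >= 0))
  expect_true(all(rep_tab$p > 0 & rep_tab$p <= 1))
  # the q ratio is consistent with the reported means and se_diff
  expect_equal(rep_tab$q,
               sqrt(2) * abs(rep_tab$mean_1 - rep_tab$mean_2) / rep_tab$se_diff)
})
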