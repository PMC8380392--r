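test_that("syndrome intensity follows the exponential recovery kinetics", {
  expect_equal(syndrome_intensity(5, s0 = 0, lambda = 0, s_inf = 0), 0)
  expect_equal(syndrome_intensity(0, 1, 0.2, 0.1), 0)   # preop
  expect_equal(syndrome_intensity(7, s0 = 1, lambda = 0.15, s_inf = 0.2),
               0.2 + 0.8 * exp(-1.05))
  # long-time limit is the residual plateau
  expect_equal(syndrome_intensity(1e6, 0.9, 0.3, 0.12), 0.12)
  expect_error(syndrome_intensity(1, s0 = 0.5, lambda = 0.1, s_inf = 0.9))
  expect_error(cohort_config(groups = list(
    UVN_placebo = list(lambda = -1))), "lambda")
})

test_that("cohort simulation is byte-identical under a fixed seed", {
  cfg <- small_cohort_config()
  a <- simulate_cohort(cfg, components = c("checklists", "quads"))
  b <- simulate_cohort(cfg, components = c("checklists", "quads"))
  expect_identical(a$records, b$records)
  expect_identical(a$checklists, b$checklists)
  expect_identical(a$quads, b$quads)
  # component subsets do not perturb the remaining streams
  c3 <- simulate_cohort(cfg, components = "quads")
  expect_identical(c3$quads, a$quads)
  # a different seed gives different data
  d <- simulate_cohort(cohort_config(seed = 999,
                                     groups = cfg$groups,
                                     dwb = list(duration = 30)),
                       components = "checklists")
  expect_false(identical(d$checklists, a$checklists))
})

test_that("sham animals stay at baseline through the full pipeline", {
  cfg <- small_cohort_config()
  co <- simulate_cohort(cfg, components = c("checklists", "quads",
                                            "trajectories"))
  m <- quantify_cohort(co)
  sham <- m[m$group == "sham" & m$day > 0, ]
  # ratio metrics ~ 1, difference metrics ~ 0, scores ~ 0
  sup <- sham$value[sham$metric == "support_surface"]
  expect_equal(mean(sup), 1, tolerance = 0.1)
  tors <- sham$value[sham$metric == "mean_body_torsion"]
  expect_lt(max(abs(tors)), 2)
  expect_lt(mean(sham$value[sham$metric == "syndrome_score"]), 0.5)
  vel <- sham$value[sham$metric == "mean_velocity"]
  expect_equal(mean(vel), 1, tolerance = 0.1)
})

test_that("behavioral readouts are monotone in the latent intensity", {
  cfg <- cohort_config(dwb = list(duration = 40),
                       openfield = list(duration = 40, fs = 10))
  s_grid <- seq(0, 0.9, by = 0.1)
  lat <- tor <- abd <- rear <- area <- numeric(length(s_grid))
  for (i in seq_along(s_grid)) {
    fr <- gen_dwb_recording(s_grid[i], cfg$dwb, seed = 1000 + i)
    lat[i] <- laterality_index(fr)
    abd[i] <- mean(fr$abdomen_w)
    rear[i] <- rearing_fraction(fr)
    tr <- gen_trajectory(s_grid[i], 2, TRUE, cfg$openfield, seed = 2000 + i)
    tor[i] <- suppressWarnings(body_torsion(tr))
    area[i] <- mean(vapply(gen_paw_quads(s_grid[i], cfg$support, 3000 + i),
                           support_surface, numeric(1)))
  }
  # monotone links, tested by rank correlation against s
  expect_lt(cor(s_grid, lat, method = "spearman"), -0.8)   # leftward
  expect_gt(cor(s_grid, tor, method = "spearman"), 0.8)    # leftward bend
  expect_gt(cor(s_grid, abd, method = "spearman"), 0.8)
  expect_lt(cor(s_grid, rear, method = "spearman"), -0.8)
  expect_gt(cor(s_grid, area, method = "spearman"), 0.8)
})

test_that("checklists reflect severity thresholds", {
  cfg <- cohort_config()$checklist
  quiet <- gen_checklist(0, cfg, seed = 21)
  expect_false(any(quiet[c("tumbling", "retropulsion", "circling")]))
  severe <- gen_checklist(1, cfg, seed = 22)
  expect_true(all(severe))
})

test_that("generated images carry their planted truth", {
  cfg <- cohort_config()$images
  g <- gen_membrane_image(c(70, 90, 110), cfg, seed = 31)
  r <- membrane_intensity(g$image, g$rois)
  expect_equal(order(r$per_cell), order(c(70, 90, 110)))
  nb <- gen_nuclei_image(9, cfg, seed = 32)
  expect_equal(as.integer(count_cells(nb$image, counting_frame(1, 1, 127))),
               9L)
})

test_that("zero-noise kinetics are recovered essentially exactly", {
  cfg <- cohort_config(
    groups = list(sham = list(n = 1L), UVN_placebo = list(n = 1L),
                  UVN_met = list(n = 1L)),
    animal_sd = 0,
    openfield = list(duration = 30, fs = 10, torsion_sd = 0,
                     dropout_rate = 0))
  co <- simulate_cohort(cfg, components = "trajectories")
  v <- vestcomp:::.recovery_metric(co, "mean_body_torsion")
  for (g in c("UVN_placebo", "UVN_met")) {
    sub <- v[v$group == g & v$day >= 1, ]
    fit <- fit_syndrome_kinetics(sub$day, sub$value)
    lam_true <- cfg$groups[[g]]$lambda
    expect_equal(coef(fit)[["lambda"]], lam_true, tolerance = 0.01)
  }
})

test_that("swapping group kinetics swaps the recovered parameters", {
  base <- list(
    groups = list(sham = list(n = 2L),
                  UVN_placebo = list(n = 2L, s0 = 0.9, lambda = 0.30,
                                     s_inf = 0.1, lesioned = TRUE),
                  UVN_met = list(n = 2L, s0 = 0.9, lambda = 0.12,
                                 s_inf = 0.1, lesioned = TRUE)),
    animal_sd = 0,
    openfield = list(duration = 20, fs = 10, torsion_sd = 0,
                     dropout_rate = 0))
  swapped <- base
  swapped$groups$UVN_placebo$lambda <- 0.12
  swapped$groups$UVN_met$lambda <- 0.30
  est <- function(cfg_list) {
    co <- simulate_cohort(do.call(cohort_config, cfg_list),
                          components = "trajectories")
    v <- vestcomp:::.recovery_metric(co, "mean_body_torsion")
    vapply(c("UVN_placebo", "UVN_met"), function(g) {
      sub <- v[v$group == g & v$day >= 1, ]
      m <- tapply(sub$value, sub$day, mean)
      coef(fit_syndrome_kinetics(as.numeric(names(m)),
                                 as.numeric(m)))[["lambda"]]
    }, numeric(1))
  }
  e1 <- est(base); e2 <- est(swapped)
  expect_equal(unname(e1), rev(unname(e2)), tolerance = 0.05)
})
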