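test_that("RMSE and joint RMSE follow their defining formulas", {
  expect_equal(rmse(0, 3.7), 3.7)
  expect_equal(rmse(-4, 3), 5)
  expect_error(rmse(1, -1), ">= 0")
  expect_equal(joint_rmse(6.4, 6.3, 2), 19.1)
  expect_equal(joint_rmse(8, 0, 1), 8)
  ## monotone increasing in each argument
  expect_true(joint_rmse(7, 6, 2) > joint_rmse(6.9, 6, 2))
  expect_true(joint_rmse(7, 6, 2) > joint_rmse(7, 5.9, 2))
})

test_that("metrics rows satisfy rmse^2 = mu^2 + sigma^2 and pooling counts", {
  cohort <- pinned_cohort()
  cfg <- search_config(n_reps = 50, seed = 7)
  rows <- rbind(
    schedule_metrics(cohort, hybrid_schedule(c(3, 96, 192), 2), cfg),
    schedule_metrics(cohort, planar_schedule(c(3, 96, 192)), cfg),
    schedule_metrics(cohort, single_tp_schedule(52), cfg))
  expect_equal(rows$rmse_K^2, rows$mu_K^2 + rows$sigma_K^2)
  expect_equal(rows$rmse_T^2, rows$mu_T^2 + rows$sigma_T^2)
  expect_equal(rows$rmse_joint, 2 * rows$rmse_K + rows$rmse_T)
  expect_equal(rows$n_dev_K, rep(13L * 50L, 3))
  expect_equal(rows$n_dev_T, rep(26L * 50L, 3))
  expect_true(all(rows$rmse_K >= abs(rows$mu_K)))
})

test_that("exact estimators give zero RMSE without noise on mono-exponential truth", {
  cohort <- mono_cohort(2)
  cfg0 <- search_config(n_reps = 3, seed = 1)
  noise0 <- noise_config(cv_planar_total = 0, cv_spect = 0)
  for (sch in list(hybrid_schedule(c(20, 192), 1),
                   hybrid_schedule(c(3, 96, 192), 2),
                   planar_schedule(c(4, 68, 144)))) {
    m <- schedule_metrics(cohort, sch, cfg0, noise0)
    expect_lt(m$rmse_K, 1e-9)
    expect_lt(m$rmse_T, 1e-9)
    expect_identical(m$n_clamped, 0L)
  }
})

test_that("hybrid estimation cancels a purely systematic planar error", {
  cohort <- mono_cohort(2)
  cfg <- search_config(n_reps = 100, seed = 5)
  noise <- noise_config(cv_planar_total = 0.2, cv_spect = 0, f_syst = 1)
  m <- schedule_metrics(cohort, hybrid_schedule(c(4, 96, 192), 2), cfg,
                        noise)
  expect_lt(m$rmse_K, 1e-9)
  expect_lt(m$rmse_T, 1e-9)
})

test_that("Monte-Carlo engine matches an independent brute-force oracle", {
  ## one patient, mono-exponential truth, 2-TP hybrid, purely stochastic
  ## planar noise; the oracle composes the closed-form estimator directly
  teff <- 40
  C <- 150; A0 <- 7300
  lphys <- lu177_lambda_phys()
  leff <- log(2) / teff
  t <- c(20, 192); t_sp <- 20.5
  sd_st <- sqrt(log(1 + 0.2^2)); sd_sp <- sqrt(log(1 + 0.05^2))

  set.seed(987)
  n_or <- 2e5
  z <- matrix(rnorm(2 * n_or), n_or, 2)
  zs <- rnorm(n_or)
  y <- log(C) - leff * matrix(t, n_or, 2, byrow = TRUE) + sd_st * z
  slope <- (y[, 2] - y[, 1]) / (t[2] - t[1])
  l1 <- pmax(-slope - lphys, 0)
  icept <- rowMeans(y) + (l1 + lphys) * mean(t)
  tiacp <- exp(icept) / ((l1 + lphys) * A0)
  a_sp <- C * exp(-leff * t_sp) * exp(sd_sp * zs)
  f_pl <- exp(icept - (l1 + lphys) * t_sp)
  delta_or <- 100 * ((a_sp / f_pl) * tiacp / (C / (leff * A0)) - 1)

  patient <- mono_patient(id = 1L, A0 = A0, teff = c(teff, 50, 60),
                          C = c(C, 40, 15))
  cohort <- structure(list(patient), class = "virtual_cohort")
  n_pkg <- 4000L
  m <- schedule_metrics(cohort, hybrid_schedule(t, 1),
                        search_config(n_reps = n_pkg, seed = 31),
                        noise_config(f_syst = 0))

  se_mu <- sd(delta_or) / sqrt(n_pkg)
  expect_lt(abs(m$mu_K - mean(delta_or)), 3 * se_mu)
  rmse_or <- sqrt(mean(delta_or^2))
  se_rmse <- sd(delta_or^2) / (2 * rmse_or * sqrt(n_pkg))
  expect_lt(abs(m$rmse_K - rmse_or), 3 * se_rmse)
})

test_that("kidney RMSE is non-decreasing in either noise magnitude", {
  cohort <- pinned_cohort()[1:4]
  class(cohort) <- "virtual_cohort"
  sch <- hybrid_schedule(c(3, 96, 192), 2)
  cfg <- search_config(n_reps = 300, seed = 11)
  r_sp <- vapply(c(0.02, 0.05, 0.10), function(cv) {
    schedule_metrics(cohort, sch, cfg, noise_config(cv_spect = cv))$rmse_K
  }, numeric(1))
  expect_true(all(diff(r_sp) >= 0))
  r_pl <- vapply(c(0.1, 0.2, 0.3), function(cv) {
    schedule_metrics(cohort, sch, cfg,
                     noise_config(cv_planar_total = cv))$rmse_K
  }, numeric(1))
  expect_true(all(diff(r_pl) >= 0))
})

test_that("single-TP tumour TIACs are underestimated at the kidney-optimal time", {
  m <- schedule_metrics(pinned_cohort(), single_tp_schedule(52),
                        search_config(n_reps = 500, seed = 7))
  expect_lt(m$mu_T, 0)
})

test_that("ranking is deterministic with documented tie-breaks", {
  fake <- data.frame(
    schedule_times = c("20,192", "3,96,192", "4,96,192", "3,96,168"),
    spect_anchor = c(1L, 2L, 2L, 2L),
    t_last = c(192, 192, 192, 168),
    rmse_joint = c(20.0, 19.1, 19.1, 19.1))
  ranked <- find_oss(fake)
  ## equal joints: earlier last TP first, then lexicographic label
  expect_equal(ranked$schedule_times, c("3,96,168", "3,96,192", "4,96,192",
                                        "20,192"))
  perm <- find_oss(fake[c(3, 1, 4, 2), ])
  expect_equal(perm$schedule_times, ranked$schedule_times)
  expect_error(find_oss(fake[0, ]), "non-empty")
})

test_that("constrained search reports nested minima over shrinking horizons", {
  cohort <- pinned_cohort()[1:3]
  class(cohort) <- "virtual_cohort"
  g <- default_grid()
  cand <- enumerate_hybrid_schedules(time_grid(c(3, 20, 48, 96, 192)), 2)
  cfg <- search_config(n_reps = 100, seed = 7)
  metrics <- run_search(cohort, cand, cfg, progress_every = 0)
  cs <- constrained_search(cohort, cand, cfg,
                           t_last_list = c(48, 96, 192), metrics = metrics)
  expect_equal(cs$n_schedules, c(6L, 12L, 20L))
  ## nested feasible sets: best RMSE non-increasing as the limit grows
  expect_true(all(diff(cs$best_rmse_joint) <= 0))
  expect_true(all(diff(cs$best_rmse_T) <= 0))
  ## unconstrained limit reproduces the global optimum
  expect_equal(cs$best_rmse_joint[3], min(metrics$rmse_joint))
  ## a limit excluding everything yields an NA row, not an error
  cs0 <- constrained_search(cohort, cand, cfg, t_last_list = c(0.5, 192),
                            metrics = metrics)
  expect_equal(cs0$n_schedules[1], 0L)
  expect_true(is.na(cs0$best_rmse_joint[1]))
})

test_that("varying the last two time points is consistent with single evaluations", {
  cohort <- pinned_cohort()[1:3]
  class(cohort) <- "virtual_cohort"
  g <- time_grid(c(3, 20, 96, 144, 192))
  base <- hybrid_schedule(c(3, 96, 192), 2)
  cfg <- search_config(n_reps = 100, seed = 7)
  grid_df <- vary_last_two(base, g, cohort, cfg)
  ## pairs with penultimate >= last are absent; base times fixed
  expect_true(all(grid_df$t_penultimate < grid_df$t_last))
  expect_true(all(grid_df$t_penultimate > 3))
  expect_equal(nrow(grid_df), choose(4, 2))
  ## base cell equals a standalone evaluation under the same seed
  base_row <- grid_df[grid_df$t_penultimate == 96 & grid_df$t_last == 192, ]
  solo <- schedule_metrics(cohort, base, cfg)
  expect_equal(base_row$rmse_joint, solo$rmse_joint)
  ## the base cell cannot beat the grid minimum
  expect_gte(base_row$rmse_joint, min(grid_df$rmse_joint))
})

test_that("search results are reproducible and order-independent", {
  cohort <- mono_cohort(2)
  cand <- enumerate_hybrid_schedules(time_grid(c(4, 96, 192)), 2)
  cfg <- search_config(n_reps = 50, seed = 3)
  r1 <- run_search(cohort, cand, cfg, progress_every = 0)
  r2 <- run_search(cohort, rev(cand), cfg, progress_every = 0)
  r2 <- r2[order(match(paste(r2$schedule_times, r2$spect_anchor),
                       paste(r1$schedule_times, r1$spect_anchor))), ]
  rownames(r2) <- NULL
  expect_equal(r1, r2)
})
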