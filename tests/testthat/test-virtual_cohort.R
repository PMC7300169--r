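test_that("ground-truth curve starts at zero, peaks where the dense scan peaks", {
  k <- region_kinetics(C = 100, lambda_bio = 0.01, lambda_up = 1.0)
  expect_equal(true_activity(k, 0), 0)
  expect_error(true_activity(k, -1), "non-negative")

  ## brute-force scan oracle for the maximum
  tt <- seq(0, 50, by = 1e-3)
  scan <- true_activity(k, tt)
  tmax <- time_of_max(k)
  expect_equal(true_activity(k, tmax), max(scan), tolerance = 1e-7)
  expect_equal(tmax, tt[which.max(scan)], tolerance = 1e-2)

  ## instantaneous-uptake limit is the pure mono-exponential
  km <- region_kinetics(C = 100, lambda_bio = 0.01, lambda_up = Inf)
  lb <- 0.01 + lu177_lambda_phys()
  expect_equal(true_activity(km, c(1, 24, 192)), 100 * exp(-lb * c(1, 24, 192)))
})

test_that("closed-form TIAC agrees with adaptive quadrature", {
  ## physical-decay-only limit: TIAC = 1/lambda_phys
  km <- region_kinetics(C = 7300, lambda_bio = 0, lambda_up = Inf)
  expect_equal(true_tiac(km, 7300), 6.647 * 24 / log(2), tolerance = 1e-12)

  set.seed(101)
  for (i in 1:100) {
    k <- region_kinetics(C = runif(1, 10, 500),
                         lambda_bio = runif(1, 0, 0.05),
                         lambda_up = runif(1, 0.2, 5))
    A0 <- runif(1, 5000, 9000)
    quad <- integrate(function(t) true_activity(k, t) / A0, 0, Inf,
                      rel.tol = 1e-10)$value
    expect_equal(true_tiac(k, A0), quad, tolerance = 1e-8)
  }

  ## linear in the amplitude
  k1 <- region_kinetics(C = 50, lambda_bio = 0.01, lambda_up = 1)
  k2 <- region_kinetics(C = 100, lambda_bio = 0.01, lambda_up = 1)
  expect_equal(2 * true_tiac(k1, 7300), true_tiac(k2, 7300))
})

test_that("effective half-life inverts the effective decay rate", {
  km <- region_kinetics(C = 1, lambda_bio = 0, lambda_up = Inf)
  expect_equal(effective_half_life(km), 6.647 * 24)
  k40 <- region_kinetics(C = 1, lambda_bio = log(2) / 40 - lu177_lambda_phys(),
                         lambda_up = Inf)
  expect_equal(effective_half_life(k40), 40)
  ## monotone decreasing in the clearance rate
  hl <- vapply(c(0, 0.005, 0.01, 0.02),
               function(lb) effective_half_life(
                 region_kinetics(1, lb, Inf)), numeric(1))
  expect_true(all(diff(hl) < 0))
})

test_that("sampled cohort reproduces the configured kinetic statistics", {
  cfg <- cohort_config(seed = 20200617L)
  cohort <- sample_cohort(cfg)
  expect_length(cohort, 13L)
  expect_equal(sum(lengths(lapply(cohort, `[[`, "lesions"))), 26L)

  teff_k <- vapply(cohort, function(p) effective_half_life(p$kidney),
                   numeric(1))
  expect_true(all(teff_k >= 30 & teff_k <= 62))
  teff_t <- unlist(lapply(cohort, function(p)
    vapply(p$lesions, effective_half_life, numeric(1))))
  expect_true(all(teff_t >= 34 & teff_t <= 94))

  tmax_k <- vapply(cohort, function(p) time_of_max(p$kidney), numeric(1))
  expect_true(all(tmax_k >= 0.6 & tmax_k <= 3))
  tmax_t <- unlist(lapply(cohort, function(p)
    vapply(p$lesions, time_of_max, numeric(1))))
  expect_true(all(tmax_t >= 0.5 & tmax_t <= 9))

  ## kidney uptake condition: >= 96.8 % of the maximum already at 1 h
  frac_1h <- vapply(cohort, function(p) {
    true_activity(p$kidney, 1) / true_activity(p$kidney,
                                               time_of_max(p$kidney))
  }, numeric(1))
  expect_true(all(frac_1h >= 0.968))

  ## injected activities positive and near the configured distribution
  a0 <- vapply(cohort, `[[`, numeric(1), "A0")
  expect_true(all(a0 > 0))
  expect_true(abs(mean(a0) - 7300) < 500)

  ## region activity never exceeds the injected activity
  peak <- vapply(cohort, function(p)
    true_activity(p$kidney, time_of_max(p$kidney)), numeric(1))
  expect_true(all(peak < a0))
})

test_that("cohort generation is reproducible and JSON round-trips exactly", {
  c1 <- sample_cohort(cohort_config(seed = 7L))
  c2 <- sample_cohort(cohort_config(seed = 7L))
  expect_identical(c1, c2)
  c3 <- sample_cohort(cohort_config(seed = 8L))
  expect_false(identical(c1, c3))

  path <- tempfile(fileext = ".json")
  write_cohort(c1, path)
  back <- read_cohort(path)
  expect_equal(back, c1, tolerance = 1e-12)

  ## infinite uptake rates survive serialization
  mono <- mono_cohort(2)
  attr(mono, "config") <- cohort_config(n_patients = 2L, seed = 1L)
  p2 <- tempfile(fileext = ".json")
  write_cohort(mono, p2)
  back2 <- read_cohort(p2)
  expect_identical(back2[[1]]$kidney$lambda_up, Inf)
})

test_that("infeasible configurations are rejected", {
  expect_error(cohort_config(kidney_teff = c(100, 150, 200)), "infeasible")
  expect_error(region_kinetics(C = -1, lambda_bio = 0.01), "positive")
  expect_error(region_kinetics(C = 1, lambda_bio = 0.5, lambda_up = 0.2),
               "exceed")
})
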