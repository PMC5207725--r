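test_that("noise-free data recover the exact decay parameters", {
  w <- noise_free_wells(k = 0.02, c0 = 100)
  fit <- fit_depletion(w, "f1", "drug")
  expect_equal(fit$a_ug_per_L, 100, tolerance = 1e-8)
  expect_equal(fit$k_h, 0.02, tolerance = 1e-8)
  expect_equal(fit$t_half_h, log(2) / 0.02, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-12)
  expect_equal(fit$n_points, 36L)
  expect_equal(fit$incubation_end_h, 24)
})

test_that("nonlinear fit agrees with a 2-D grid-search oracle on noisy data", {
  cfg <- simulation_config(
    n_fish = 1, k_mean_h = 0.045, k_sd_h = 0, dose_mean_ug_per_L = 98,
    measurement_cv = 0.10, seed = 21
  )
  w <- simulate_fish(cfg, "f1")$wells
  ew <- w[w$well_role == "exposure", ]
  fit <- fit_depletion(w, "f1", "propranolol")
  expect_lt(abs(fit$k_h - 0.045), 3 * fit$k_se_h)

  grid <- grid_search_fit(ew$time_h, ew$concentration_ug_per_L,
                          a_range = c(80, 120), k_range = c(0.02, 0.08))
  a_res <- (120 - 80) / 200
  k_res <- (0.08 - 0.02) / 200
  expect_lt(abs(fit$a_ug_per_L - grid["a"]), a_res)
  expect_lt(abs(fit$k_h - grid["k"]), k_res)
  expect_lte(fit$rss, grid["rss"] + 1e-9)
})

test_that("nonlinear fit matches the log-linear oracle on noise-free data", {
  for (k in c(0.005, 0.022, 0.1)) {
    w <- noise_free_wells(k = k, c0 = 98)
    ew <- w[w$well_role == "exposure", ]
    ols_k <- -unname(stats::coef(stats::lm(log(concentration_ug_per_L) ~ time_h,
                                           data = ew))[2])
    fit <- fit_depletion(w, "f1", "drug")
    expect_lt(abs(fit$k_h - ols_k) / ols_k, 1e-8)
  }
})

test_that("fitted k is invariant under uniform concentration rescaling", {
  cfg <- simulation_config(n_fish = 1, seed = 8)
  w <- simulate_fish(cfg, "f1")$wells
  f1 <- fit_depletion(w, "f1", "propranolol")
  w2 <- w
  w2$concentration_ug_per_L <- w2$concentration_ug_per_L * 3.7
  f2 <- fit_depletion(w2, "f1", "propranolol")
  expect_equal(f2$k_h, f1$k_h, tolerance = 1e-6)
  expect_equal(f2$a_ug_per_L, 3.7 * f1$a_ug_per_L, tolerance = 1e-6)
})

test_that("larger true rate constants yield larger fitted constants", {
  ks <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  fitted <- vapply(ks, function(k) {
    fit_depletion(noise_free_wells(k = k), "f1", "drug")$k_h
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("half-life identity matches the printed per-fish values", {
  expect_equal(round(half_life(0.019), 1), 36.5)
  expect_equal(round(half_life(0.027), 1), 25.7)
  expect_equal(half_life(log(2)), 1.0)
  expect_error(half_life(0), "k_h > 0")
  expect_error(half_life(-0.01), "k_h > 0")
})

test_that("t_half * k equals ln 2 for every fitted fish", {
  cfg <- simulation_config(n_fish = 8, seed = 13)
  sim <- simulate_cohort(cfg)
  fits <- fit_all(sim$wells, alpha = 0.05)
  ok <- !fits$nsd & fits$k_h > 0
  expect_true(any(ok))
  expect_equal(fits$t_half_h[ok] * fits$k_h[ok], rep(log(2), sum(ok)))
})

test_that("percent depletion is the relative drop in endpoint means", {
  w <- dplyr::bind_rows(
    tibble::tibble(fish_id = "f", compound = "d", well_role = "exposure",
                   time_h = 0, replicate = 1:2, concentration_ug_per_L = c(97, 99)),
    tibble::tibble(fish_id = "f", compound = "d", well_role = "exposure",
                   time_h = 12, replicate = 1:2, concentration_ug_per_L = c(80, 78)),
    tibble::tibble(fish_id = "f", compound = "d", well_role = "exposure",
                   time_h = 24, replicate = 1:2, concentration_ug_per_L = c(57.8, 57.84))
  )
  expect_equal(percent_depletion(w, "f", "d", 24), 100 * (1 - 57.82 / 98))
  # identical endpoints: zero depletion
  w0 <- noise_free_wells(k = 0)
  expect_equal(percent_depletion(w0, "f1", "drug", 24), 0)
  # closed form for k = 0.022 over 24 h
  wk <- noise_free_wells(k = 0.022)
  expect_equal(percent_depletion(wk, "f1", "drug", 24), 100 * (1 - exp(-0.022 * 24)))
  expect_error(percent_depletion(wk, "f1", "drug", 7), "end_h")
})

test_that("unambiguous depletion is never classified NSD", {
  w <- noise_free_wells(k = 0.02)
  fit <- fit_depletion(w, "f1", "drug")
  mc <- w[w$well_role == "medium_control", ]
  expect_false(classify_nsd(fit, w, mc, alpha = 0.05))
})

test_that("a null compound is classified NSD", {
  cfg <- simulation_config(n_fish = 1, k_mean_h = 0, k_sd_h = 0, seed = 17)
  w <- simulate_fish(cfg, "f1")$wells
  fit <- fit_depletion(w, "f1", "propranolol")
  mc <- w[w$well_role == "medium_control", ]
  expect_true(classify_nsd(fit, w, mc, alpha = 0.05))
})

test_that("missing medium controls fall back to the k criterion with a warning", {
  w <- noise_free_wells(k = 0.02)
  fit <- fit_depletion(w, "f1", "drug")
  expect_warning(res <- classify_nsd(fit, w, NULL, alpha = 0.05), "medium controls")
  expect_false(res)
})

test_that("insufficient time courses are rejected with clear errors", {
  w <- noise_free_wells(k = 0.02, times = c(0, 24))
  expect_error(fit_depletion(w, "f1", "drug"), "3 distinct time points")
  w2 <- noise_free_wells(k = 0.02, times = c(1, 2, 4, 24))
  expect_error(fit_depletion(w2, "f1", "drug"), "time 0")
  expect_error(fit_depletion(w2, "nope", "drug"), "no exposure wells")
})

test_that("extended incubations take the endpoint from the data", {
  w <- noise_free_wells(k = 0.01, times = c(0, 4, 24, 48, 72))
  fit <- fit_depletion(w, "f1", "drug")
  expect_equal(fit$incubation_end_h, 72)
  expect_equal(fit$percent_depletion, 100 * (1 - exp(-0.01 * 72)))
})
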