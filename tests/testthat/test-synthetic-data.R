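test_that("generated cohorts have the configured structure and window layout", {
  cfg <- synthetic_cohort_config(n_patients = 28, seed = 10)
  cohort <- generate_clinical_cohort(cfg)
  obs <- cohort$observations
  expect_equal(length(unique(obs$patient_id)), 28)
  per_curve <- dplyr::count(obs, .data$patient_id, .data$structure_label)
  expect_true(all(per_curve$n == 4))
  # one scan inside each window, times sorted
  win <- time_periods()
  by_curve <- split(obs$time_h, paste(obs$patient_id, obs$structure_label))
  for (ts in by_curve) {
    expect_true(!is.unsorted(ts))
    expect_true(all(ts >= win$low & ts <= win$high))
    expect_identical(assign_time_period(ts), win$label)
  }
  # tumors between 1 and 5 per patient
  n_tum <- obs |>
    dplyr::filter(.data$structure == "tumor") |>
    dplyr::distinct(.data$patient_id, .data$structure_label) |>
    dplyr::count(.data$patient_id)
  expect_true(all(n_tum$n >= 1 & n_tum$n <= 5))
})

test_that("degenerate config (no spread, no noise) reproduces the generator exactly", {
  d <- cohort_distribution(
    "kidney", fit_labels = "mono",
    mono = list(C = lognormal_spec(0, 70), lambda1 = lognormal_spec(0, 0.014)))
  cfg <- synthetic_cohort_config(n_patients = 3, dists = d, noise = NULL,
                                 seed = 2)
  cohort <- generate_clinical_cohort(cfg)
  expect_true(all(cohort$ground_truth$C == 70))
  fits <- fit_tac(cohort$observations, method = "mono")
  expect_equal(fits$C, rep(70, 3), tolerance = 1e-6)
  expect_equal(fits$lambda1, rep(0.014, 3), tolerance = 1e-6)
})

test_that("cohort generation is seed-reproducible and seed-sensitive", {
  cfg <- synthetic_cohort_config(n_patients = 5, seed = 42)
  c1 <- generate_clinical_cohort(cfg)
  c2 <- generate_clinical_cohort(cfg)
  expect_identical(c1$observations, c2$observations)
  cfg2 <- synthetic_cohort_config(n_patients = 5, seed = 43)
  c3 <- generate_clinical_cohort(cfg2)
  expect_false(identical(c1$observations$time_h, c3$observations$time_h))
})

test_that("default amplitudes preserve the configured concentration ordering", {
  cfg <- synthetic_cohort_config(n_patients = 20, seed = 6)
  truth <- generate_clinical_cohort(cfg)$ground_truth
  med <- truth |>
    dplyr::group_by(.data$structure) |>
    dplyr::summarise(C = stats::median(.data$C), .groups = "drop")
  getC <- function(s) med$C[med$structure == s]
  expect_gt(getC("healthy_liver"), getC("spleen"))
  expect_gt(getC("spleen"), getC("left_kidney"))
})

test_that("phantom tables let the noise power law be recovered", {
  truth <- noise_model(a = 0.05, b = -0.4)
  fit4 <- fit_noise_model(generate_phantom_table(truth, seed = 1))
  expect_equal(fit4$a, 0.05, tolerance = 0.15)
  expect_equal(fit4$b, -0.4, tolerance = 0.15)
  fit1000 <- fit_noise_model(
    generate_phantom_table(truth, n_repeats = 1000, seed = 1))
  expect_equal(fit1000$a, 0.05, tolerance = 0.01)
  expect_equal(fit1000$b, -0.4, tolerance = 0.01)
})

test_that("an (effectively) noise-free phantom cannot support a noise fit", {
  silent <- noise_model(a = 1e-300, b = -0.4)
  tab <- generate_phantom_table(silent, seed = 1)
  expect_warning(expect_error(fit_noise_model(tab), "fewer than 2"),
                 "excluded")
})

test_that("the generate -> fit -> derive -> sample pipeline is closed", {
  cfg <- synthetic_cohort_config(n_patients = 28, noise = NULL, seed = 9)
  cohort <- generate_clinical_cohort(cfg)
  fits <- fit_tac(cohort$observations)
  expect_true(mean(fits$valid) > 0.9)
  derived <- derive_cohort_distribution(
    dplyr::filter(fits, .data$structure == "left_kidney"))
  set.seed(77)
  draws <- sample_tac(derived, "left_kidney", 200)
  # sampled parameters stay within the derived (cohort min/max) bounds,
  # which themselves lie inside the generating support
  mono_fits <- dplyr::filter(fits, .data$structure == "left_kidney",
                             .data$kind == "mono")
  mono_draws <- dplyr::filter(draws, .data$kind == "mono")
  expect_gte(min(mono_draws$lambda1), min(mono_fits$lambda1))
  expect_lte(max(mono_draws$lambda1), max(mono_fits$lambda1))
  expect_true(all(mono_draws$C >= min(mono_fits$C) &
                    mono_draws$C <= max(mono_fits$C)))
})

test_that("default phantom scan lengths span the configured count reduction", {
  sl <- default_phantom_scan_lengths()
  expect_length(sl, 10)
  expect_equal(sl[1], 25)
  expect_equal(sl[1] / sl[10], 16)
  expect_true(all(diff(sl) < 0))
})
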