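test_that("derived lognormal stats match hand-computed two-value case", {
  fits <- tibble::tibble(
    structure = "kidney", kind = "mono",
    C = c(50, 80), lambda1 = c(log(2) / 50, log(2) / 100), lambda2 = NA_real_,
    valid = TRUE)
  d <- derive_cohort_distribution(fits)
  lam <- d$kidney$mono$lambda1
  expect_equal(lam$mu, log(2) / sqrt(5000), tolerance = 1e-9)
  expect_equal(lam$mu, 0.009802, tolerance = 1e-4)
  expect_equal(lam$s, stats::sd(log(c(log(2) / 50, log(2) / 100))))
  expect_equal(lam$s, 0.4901, tolerance = 1e-4)
  expect_equal(lam$lower, log(2) / 100)
  expect_equal(lam$upper, log(2) / 50)
})

test_that("identical cohort values give a degenerate (s = 0) distribution", {
  fits <- tibble::tibble(structure = "spleen", kind = "mono",
                         C = c(60, 60), lambda1 = c(0.01, 0.01),
                         lambda2 = NA_real_, valid = TRUE)
  d <- derive_cohort_distribution(fits)
  expect_equal(d$spleen$mono$C$s, 0)
  set.seed(2)
  draws <- sample_tac(d, "spleen", 50)
  expect_true(all(draws$C == 60))
  expect_true(all(draws$lambda1 == 0.01))
  expect_true(all(draws$tia == 6000))
})

test_that("wider literature half-life ranges replace cohort truncation bounds", {
  fits <- tibble::tibble(structure = "kidney", kind = "mono",
                         C = c(50, 80), lambda1 = c(log(2) / 50, log(2) / 100),
                         lambda2 = NA_real_, valid = TRUE)
  d <- derive_cohort_distribution(fits,
                                  halflife_cutoffs = list(kidney = c(20, 200)))
  lam <- d$kidney$mono$lambda1
  expect_equal(lam$lower, log(2) / 200)
  expect_equal(lam$upper, log(2) / 20)
  # a narrower literature range must NOT shrink the cohort bounds
  d2 <- derive_cohort_distribution(fits,
                                   halflife_cutoffs = list(kidney = c(60, 90)))
  expect_equal(d2$kidney$mono$lambda1$lower, log(2) / 100)
  expect_equal(d2$kidney$mono$lambda1$upper, log(2) / 50)
})

test_that("bootstrap reproduces the cohort bi fraction and truncation bounds", {
  d <- cohort_distribution(
    "tumor", fit_labels = c("mono", "mono", "mono", "bi", "bi"),
    mono = list(C = lognormal_spec(0.3, 50), lambda1 = lognormal_spec(0.3, 0.01)),
    bi = list(C = lognormal_spec(0.3, 50), lambda1 = lognormal_spec(0.3, 0.01),
              lambda2 = lognormal_spec(0.2, 0.17)))
  set.seed(8)
  draws <- sample_tac(d, "tumor", 1e4)
  expect_equal(mean(draws$kind == "bi"), 0.4, tolerance = 0.02)
  spec <- d$tumor$mono$lambda1
  expect_true(all(draws$lambda1 >= spec$lower & draws$lambda1 <= spec$upper))
  bi <- draws[draws$kind == "bi", ]
  expect_true(all(bi$lambda2 > bi$lambda1))
  expect_true(all(analytic_tia(draws)$tia > 0))
})

test_that("rejection sampling errors out on inconsistent truncation bounds", {
  expect_error(lognormal_spec(s = 0.1, mu = 1, lower = 2, upper = 3),
               "lower <= mu")
})

test_that("zero-noise mono-only simulation recovers truth exactly for (24, 96)", {
  d <- mono_only_dist()
  sim <- run_simulation_study(d, n_curves = 25, noise = NULL,
                              schedules = "2tp", seed = 3,
                              keep_records = TRUE)
  rec <- dplyr::filter(sim$records, t1 == 24, t2 == 96)
  expect_equal(nrow(rec), 25)
  expect_true(all(rec$valid))
  expect_equal(rec$tia_est, rec$tia_true, tolerance = 1e-6)
})

test_that("zero-noise Madsen is exact at each curve's own half-life", {
  d <- mono_only_dist(structure = "kidney", s = 0)  # all curves share T_eff
  pop <- population_kinetics("kidney", 50)
  sim <- run_simulation_study(d, n_curves = 10, noise = NULL,
                              schedules = "stp", pop = pop, seed = 4,
                              keep_records = TRUE)
  rec <- dplyr::filter(sim$records, method == "madsen", t1 == 50)
  expect_equal(rec$tia_est, rec$tia_true, tolerance = 1e-4)
})

test_that("identical seeds reproduce the simulation bitwise; seeds matter", {
  d <- mono_only_dist()
  nm <- noise_model(0.05, -0.4)
  s1 <- run_simulation_study(d, n_curves = 10, noise = nm,
                             schedules = "2tp", seed = 11)
  s2 <- run_simulation_study(d, n_curves = 10, noise = nm,
                             schedules = "2tp", seed = 11)
  s3 <- run_simulation_study(d, n_curves = 10, noise = nm,
                             schedules = "2tp", seed = 12)
  expect_identical(s1$summaries, s2$summaries)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$summaries$mpe, s3$summaries$mpe))
})

test_that("curve generation is unaffected by which schedule families run", {
  d <- mono_only_dist()
  nm <- noise_model(0.05, -0.4)
  a <- run_simulation_study(d, n_curves = 8, noise = nm,
                            schedules = "2tp", seed = 5)
  b <- run_simulation_study(d, n_curves = 8, noise = nm,
                            schedules = c("stp", "2tp", "3tp"), seed = 5)
  expect_identical(a$truth, b$truth)
  sum_a <- dplyr::filter(a$summaries, method == "2tp")
  sum_b <- dplyr::filter(b$summaries, method == "2tp")
  expect_identical(sum_a, sum_b)
})

test_that("MPE standard error shrinks roughly as 1/sqrt(n_curves)", {
  d <- mono_only_dist()
  nm <- noise_model(0.05, -0.4)
  mpe_at <- function(n, seed) {
    sim <- run_simulation_study(d, n_curves = n, noise = nm,
                                schedules = "2tp", seed = seed)
    dplyr::filter(sim$summaries, t1 == 24, t2 == 96)$mpe
  }
  m50 <- vapply(1:12, function(s) mpe_at(50, 100 + s), numeric(1))
  m200 <- vapply(1:12, function(s) mpe_at(200, 200 + s), numeric(1))
  ratio <- stats::sd(m50) / stats::sd(m200)
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.4)
})

test_that("cohort distribution JSON round trip preserves specs and labels", {
  d <- default_generating_distribution()
  tmp <- withr::local_tempfile(fileext = ".json")
  cohort_distribution_to_json(d, tmp)
  d2 <- cohort_distribution_from_json(tmp)
  expect_identical(names(d2), names(d))
  expect_equal(d2$tumor$fit_labels, d$tumor$fit_labels)
  expect_equal(unclass(d2$tumor$mono$lambda1),
               unclass(d$tumor$mono$lambda1))
  expect_equal(unclass(d2$tumor$bi$lambda2), unclass(d$tumor$bi$lambda2))
})
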