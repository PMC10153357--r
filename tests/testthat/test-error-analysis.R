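test_that("percent error is the plain relative error in percent", {
  expect_equal(percent_error(110, 100), 10)
  expect_equal(percent_error(100, 100), 0)
  expect_equal(percent_error(50, 200), -75)
  expect_error(percent_error(10, 0), "> 0")
})

test_that("summary metrics match hand arithmetic", {
  df <- tibble::tibble(tia_est = c(95, 100, 105), tia_true = 100,
                       valid = TRUE)
  s <- summarize_tia_errors(df)
  expect_equal(s$mpe, 0)
  expect_equal(s$sd, 5)
  expect_equal(s$mape, 10 / 3)
  expect_equal(s$rmse, sqrt(50 / 3))
  expect_equal(s$rmse, 4.082, tolerance = 1e-3)
  expect_equal(s$ci95_low, -1.96 * 5 / sqrt(3))
  expect_true(s$ci95_low <= s$mpe && s$mpe <= s$ci95_high)
})

test_that("exact estimates give all-zero metrics", {
  df <- tibble::tibble(tia_est = c(10, 20, 30), tia_true = c(10, 20, 30),
                       valid = TRUE)
  s <- summarize_tia_errors(df)
  expect_equal(c(s$rmse, s$mpe, s$sd, s$mape), c(0, 0, 0, 0))
})

test_that("invalid records are counted but excluded from metrics by default", {
  df <- tibble::tibble(tia_est = c(95, 105, NA), tia_true = 100,
                       valid = c(TRUE, TRUE, FALSE))
  s <- summarize_tia_errors(df)
  expect_equal(s$n_total, 3)
  expect_equal(s$n_valid, 2)
  expect_equal(s$mpe, 0)
  expect_equal(s$mape, 5)
  # penalize mode charges the cap instead
  p <- summarize_tia_errors(df, policy = "penalize", cap_pct = 300)
  expect_equal(p$n_valid, 3)
  expect_equal(p$mpe, (-5 + 5 + 300) / 3)
  expect_error(summarize_tia_errors(
    tibble::tibble(tia_est = 1, tia_true = 1, valid = FALSE)),
    "zero valid")
})

test_that("grouped summaries return one row per group", {
  df <- tibble::tibble(
    structure = rep(c("kidney", "tumor"), each = 3),
    tia_est = c(95, 100, 105, 90, 100, 110), tia_true = 100, valid = TRUE)
  s <- df |>
    dplyr::group_by(.data$structure) |>
    summarize_tia_errors()
  expect_equal(nrow(s), 2)
  expect_equal(s$sd, c(5, 10))
})

test_that("mape >= |mpe| and order invariance hold on random record sets", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    df <- tibble::tibble(tia_est = stats::runif(n, 50, 150),
                         tia_true = stats::runif(n, 80, 120),
                         valid = stats::runif(n) > 0.2)
    if (sum(df$valid) < 2) next
    s <- summarize_tia_errors(df)
    expect_gte(s$mape, abs(s$mpe) - 1e-12)
    expect_gte(s$rmse, 0)
    shuffled <- df[sample.int(n), ]
    expect_equal(summarize_tia_errors(shuffled), s)
  }
})

test_that("optimal schedule search minimises RMSE with lexicographic tie-break", {
  s <- tibble::tibble(structure = "kidney", method = "2tp",
                      t1 = c(24, 4), t2 = c(96, 8), t3 = NA_real_,
                      rmse = c(100, 900))
  expect_equal(find_optimal_schedule(s)$t1, 24)
  tie <- tibble::tibble(structure = "kidney", method = "2tp",
                        t1 = c(24, 24), t2 = c(120, 96), t3 = NA_real_,
                        rmse = c(100, 100))
  best <- find_optimal_schedule(tie)
  expect_equal(c(best$t1, best$t2), c(24, 96))
  single <- tibble::tibble(structure = "s", method = "m", t1 = 4,
                           t2 = NA_real_, t3 = NA_real_, rmse = 7)
  expect_equal(find_optimal_schedule(single)$rmse, 7)
  expect_error(find_optimal_schedule(single[0, ]), "non-empty")
})

test_that("zero-noise exact cohorts tie across schedules and resolve lexicographically", {
  d <- mono_only_dist()
  sim <- run_simulation_study(d, n_curves = 10, noise = NULL,
                              schedules = "2tp", seed = 13)
  # every schedule is exact to floating-point residue
  expect_lt(max(abs(sim$summaries$mpe)), 1e-4)
  expect_lt(max(sim$summaries$rmse), 1e-4)
  # with the residue rounded away the tie resolves to the earliest tuple
  tied <- dplyr::mutate(sim$summaries, rmse = 0)
  best <- find_optimal_schedule(tied)
  expect_equal(c(best$t1, best$t2), c(4, 8))
})

test_that("reports expose the optimal table, heatmap matrices and provenance", {
  d <- mono_only_dist()
  sim <- run_simulation_study(d, n_curves = 10, noise = noise_model(0.05, -0.4),
                              schedules = c("stp", "2tp"), seed = 19,
                              pop = population_kinetics("kidney", 50))
  rep <- build_reports(sim)
  expect_setequal(rep$optimal$method, c("2tp", "hanscheid", "madsen"))
  expect_true(all(c("schedule", "rmse", "mpe_sd", "mape") %in%
                    names(rep$optimal)))
  # heatmap is strictly upper-triangular in (t1, t2)
  expect_true(all(rep$heatmap_2tp$t1 < rep$heatmap_2tp$t2))
  expect_equal(nrow(rep$heatmap_2tp), 1770)
  expect_equal(rep$provenance$seed, 19)
  expect_equal(rep$provenance$population_kinetics$T_pop_h, 50)
})

test_that("check_schedule retrieves the summary row for a requested schedule", {
  d <- mono_only_dist()
  sim <- run_simulation_study(d, n_curves = 10, noise = noise_model(0.05, -0.4),
                              seed = 23, pop = population_kinetics("kidney", 50))
  expect_equal(nrow(check_schedule(sim, c(24, 96))), 1)
  expect_equal(nrow(check_schedule(sim, c(8, 24, 48))), 1)
  expect_equal(nrow(check_schedule(sim, 96)), 2)   # both STP methods
  expect_equal(nrow(check_schedule(sim, 96, method = "madsen")), 1)
  expect_error(check_schedule(sim, c(5, 7)), "not on the evaluated grid")
})
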