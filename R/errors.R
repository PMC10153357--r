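#' Percent error of a TIA estimate
#'
#' `100 * (tia_est - tia_true) / tia_true`.
#'
#' @param tia_est Estimated TIA, MBq h (vectorised).
#' @param tia_true Ground-truth TIA, MBq h (`> 0`).
#' @return Percent error.
#' @examples
#' percent_error(110, 100)   # +10
#' @export
percent_error <- function(tia_est, tia_true) {
  if (any(tia_true <= 0, na.rm = TRUE)) {
    stop("`tia_true` must be > 0.", call. = FALSE)
  }
  100 * (tia_est - tia_true) / tia_true
}

#' Summarise TIA estimation errors
#'
#' Computes, over the valid records of each group: RMSE on absolute TIA
#' (MBq h, so it is scale-weighted toward high-uptake cases), mean percent
#' error (MPE), the sample (n-1) SD of percent errors, mean absolute percent
#' error (MAPE), and a normal-approximation 95% confidence interval for the
#' MPE (`mpe +/- 1.96 sd / sqrt(n_valid)`). Invalid records count in
#' `n_total` only under the default `"exclude"` policy; under `"penalize"`
#' they are scored at `cap_pct` percent error (with the matching absolute
#' error) so that failure-prone schedules surface in RMSE rankings.
#'
#' @param data Data frame (possibly grouped) with columns `tia_est`,
#'   `tia_true`, `valid`.
#' @param policy `"exclude"` or `"penalize"`.
#' @param cap_pct Percent error charged to invalid records when penalising.
#' @return One tibble row per group: `n_total`, `n_valid`, `rmse`, `mpe`,
#'   `sd`, `mape`, `ci95_low`, `ci95_high`.
#' @export
summarize_tia_errors <- function(data, policy = c("exclude", "penalize"),
                                 cap_pct = 1000) {
  policy <- match.arg(policy)
  req <- c("tia_est", "tia_true", "valid")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop("`data` needs columns tia_est, tia_true, valid.", call. = FALSE)
  }
  one <- function(est, tru, valid) {
    n_total <- length(est)
    if (policy == "penalize") {
      est <- ifelse(valid, est, tru * (1 + cap_pct / 100))
      valid <- rep(TRUE, n_total)
    }
    n_valid <- sum(valid)
    if (n_valid == 0) {
      stop("a group has zero valid records; cannot summarise.", call. = FALSE)
    }
    e <- est[valid]; g <- tru[valid]
    pe <- percent_error(e, g)
    mpe <- mean(pe)
    sdv <- if (n_valid >= 2) stats::sd(pe) else NA_real_
    half <- 1.96 * sdv / sqrt(n_valid)
    tibble::tibble(
      n_total = n_total, n_valid = n_valid,
      rmse = sqrt(mean((e - g)^2)),
      mpe = mpe, sd = sdv, mape = mean(abs(pe)),
      ci95_low = mpe - half, ci95_high = mpe + half
    )
  }
  if (dplyr::is_grouped_df(data)) {
    dplyr::summarise(
      data,
      one(.data$tia_est, .data$tia_true, .data$valid),
      .groups = "drop"
    )
  } else {
    one(data$tia_est, data$tia_true, data$valid)
  }
}

#' Find the lowest-RMSE sampling schedule
#'
#' Returns, per group (e.g. structure and method), the summary row with
#' minimal RMSE. Exact ties resolve to the lexicographically earliest time
#' tuple `(t1, t2, t3)`.
#'
#' @param summaries Summary tibble with an `rmse` column and schedule time
#'   columns among `t1`, `t2`, `t3`; may be grouped, or pass `by`.
#' @param by Character vector of grouping columns (default
#'   `c("structure", "method")` intersected with what is present).
#' @return One tibble row per group.
#' @export
find_optimal_schedule <- function(summaries,
                                  by = intersect(c("structure", "method"),
                                                 names(summaries))) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0) {
    stop("`summaries` must be a non-empty data frame.", call. = FALSE)
  }
  if (!"rmse" %in% names(summaries)) {
    stop("`summaries` needs an `rmse` column.", call. = FALSE)
  }
  tcols <- intersect(c("t1", "t2", "t3"), names(summaries))
  summaries |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::arrange(.data$rmse,
                   dplyr::across(dplyr::all_of(tcols)),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Build report tables from schedule summaries
#'
#' Shapes the evaluation output the way dosimetry reports present it:
#' an optimal-schedule table (one row per structure and method with RMSE,
#' MPE (SD) and MAPE), the full 2TP MPE and SD matrices keyed by `(t1, t2)`
#' for heatmap export, and run provenance (seed and population kinetics
#' used).
#'
#' @param sim A `tia_simulation` from [run_simulation_study()], or a summary
#'   tibble shaped like its `summaries` element.
#' @return A list with elements `optimal` (tibble), `heatmap_2tp` (long
#'   tibble: `structure`, `t1`, `t2`, `mpe`, `sd`), and `provenance` (list;
#'   empty when a bare tibble was supplied).
#' @export
build_reports <- function(sim) {
  if (inherits(sim, "tia_simulation")) {
    summaries <- sim$summaries
    provenance <- sim$config
  } else {
    summaries <- sim
    provenance <- list()
  }
  optimal <- find_optimal_schedule(summaries) |>
    dplyr::mutate(
      schedule = paste_schedule(.data$t1, .data$t2, .data$t3),
      mpe_sd = sprintf("%.1f (%.1f)", .data$mpe, .data$sd)
    ) |>
    dplyr::select(dplyr::any_of(c("structure", "method", "schedule", "rmse",
                                  "mpe", "sd", "mpe_sd", "mape", "n_valid",
                                  "n_total")))
  heat <- summaries |>
    dplyr::filter(.data$method == "2tp") |>
    dplyr::select(dplyr::any_of(c("structure", "t1", "t2", "mpe", "sd")))
  list(optimal = optimal, heatmap_2tp = heat, provenance = provenance)
}

paste_schedule <- function(t1, t2, t3) {
  mapply(function(a, b, c) {
    paste(stats::na.omit(c(a, b, c)), collapse = ", ")
  }, t1, t2, t3, USE.NAMES = FALSE)
}

#' Error summary for a user-chosen sampling schedule
#'
#' Looks up the per-structure error summaries of one specific 1-, 2- or
#' 3-time-point schedule in a completed simulation — the "what if we image
#' at these times?" companion query. Times must lie on the corresponding
#' evaluation grid.
#'
#' @param sim A `tia_simulation` (its `summaries` must cover the matching
#'   schedule family).
#' @param times Numeric vector of 1-3 increasing times, hours.
#' @param method For one time point, which STP estimator(s) to report
#'   (default both).
#' @return A tibble with one row per structure (and method).
#' @export
check_schedule <- function(sim, times, method = c("hanscheid", "madsen")) {
  stopifnot(inherits(sim, "tia_simulation"))
  times <- sort(as.numeric(times))
  if (length(times) < 1 || length(times) > 3) {
    stop("`times` must contain 1 to 3 times.", call. = FALSE)
  }
  s <- sim$summaries
  out <- switch(as.character(length(times)),
    "1" = dplyr::filter(s, .data$method %in% !!method,
                        .data$t1 == times[1], is.na(.data$t2)),
    "2" = dplyr::filter(s, .data$method == "2tp",
                        .data$t1 == times[1], .data$t2 == times[2]),
    "3" = dplyr::filter(s, .data$method == "3tp", .data$t1 == times[1],
                        .data$t2 == times[2], .data$t3 == times[3])
  )
  if (nrow(out) == 0) {
    stop("schedule (", paste(times, collapse = ", "),
         ") h is not on the evaluated grid for its family.", call. = FALSE)
  }
  out
}
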