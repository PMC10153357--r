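#' Heatmap of 2TP schedule errors
#'
#' Upper-triangular `(t1, t2)` tile map of a chosen error metric for all
#' two-time-point schedules, one facet per structure. Large metric values
#' (failing schedules, typically two close late time points) are clipped to
#' `limit` so the informative range stays visible.
#'
#' @param sim A `tia_simulation` or its `summaries` tibble.
#' @param metric One of `"mpe"`, `"sd"`, `"mape"`, `"rmse"`.
#' @param limit Absolute clipping limit for the fill scale (percent), or
#'   `NULL`.
#' @return A ggplot object.
#' @export
plot_error_heatmap <- function(sim, metric = c("mpe", "sd", "mape", "rmse"),
                               limit = 25) {
  metric <- match.arg(metric)
  s <- if (inherits(sim, "tia_simulation")) sim$summaries else sim
  s <- dplyr::filter(s, .data$method == "2tp")
  if (nrow(s) == 0) stop("no 2TP summaries to plot.", call. = FALSE)
  s$value <- s[[metric]]
  if (!is.null(limit)) {
    s$value <- pmax(pmin(s$value, limit), -limit)
  }
  ggplot2::ggplot(s, ggplot2::aes(x = .data$t1, y = .data$t2,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~structure) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = toupper(metric)) +
    ggplot2::labs(x = "first time point (h)", y = "second time point (h)",
                  title = sprintf("2TP schedule %s", toupper(metric))) +
    ggplot2::theme_minimal()
}

#' Single-time-point error versus sampling time
#'
#' MPE with its 95% confidence ribbon as a function of the STP sampling
#' time, for both estimators, faceted by structure; the minimum-RMSE time is
#' marked.
#'
#' @param sim A `tia_simulation` or its `summaries` tibble.
#' @return A ggplot object.
#' @export
plot_stp_error <- function(sim) {
  s <- if (inherits(sim, "tia_simulation")) sim$summaries else sim
  s <- dplyr::filter(s, .data$method %in% c("hanscheid", "madsen"))
  if (nrow(s) == 0) stop("no STP summaries to plot.", call. = FALSE)
  opt <- find_optimal_schedule(s)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$t1, y = .data$mpe,
                                  colour = .data$method,
                                  fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci95_low,
                                      ymax = .data$ci95_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = opt, shape = 4, size = 3, stroke = 1.5) +
    ggplot2::facet_wrap(~structure, scales = "free_y") +
    ggplot2::labs(x = "sampling time (h post-injection)", y = "MPE (%)",
                  title = "Single-time-point TIA error",
                  subtitle = "X marks the minimum-RMSE sampling time") +
    ggplot2::theme_minimal()
}

#' Percent-error boxplots by period combination
#'
#' Distribution of per-curve percent errors grouped by time-period
#' combination, the layout used to compare clinical reduced-time-point
#' schedules.
#'
#' @param clin A `tia_clinical` from [run_clinical_study()], or a records
#'   tibble with columns `structure`, `method`, `periods`, `tia_est`,
#'   `tia_true`, `valid`.
#' @param method Which method's records to plot.
#' @return A ggplot object.
#' @export
plot_period_boxplot <- function(clin, method = "2tp") {
  rec <- if (inherits(clin, "tia_clinical")) clin$records else clin
  rec <- dplyr::filter(rec, .data$method == !!method, .data$valid)
  if (nrow(rec) == 0) stop("no valid records for method ", method,
                           call. = FALSE)
  rec$pe <- percent_error(rec$tia_est, rec$tia_true)
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$periods, y = .data$pe)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 4, size = 2) +
    ggplot2::facet_wrap(~structure, scales = "free_y") +
    ggplot2::labs(x = "time-period combination", y = "percent error (%)",
                  title = sprintf("%s TIA percent error by schedule", method)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' @method autoplot tia_simulation
#' @export
autoplot.tia_simulation <- function(object, ...) {
  if (any(object$summaries$method == "2tp")) {
    plot_error_heatmap(object, ...)
  } else {
    plot_stp_error(object)
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
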