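#' Sampling-time grids and schedule enumeration
#'
#' The single-time-point (STP) evaluation grid is hourly from 1 to 240 h
#' post-injection (240 times). Two-time-point schedules use a 4-hour grid
#' (4, 8, ..., 240 h; 60 times), giving all `choose(60, 2) = 1770` increasing
#' pairs. Three-time-point schedules are restricted to realistic clinic
#' hours: assuming injection at the start of day 0, scans may only happen at
#' the beginning (24k h), middle (24k + 4 h) and end (24k + 8 h) of each day
#' (30 valid times up to 240 h, starting 4 h after injection), and no two
#' scans of a schedule may fall on the same day — equivalently every pairwise
#' gap must exceed 12 h ("overnight" gaps between days are allowed). This
#' yields exactly 3294 admissible triples.
#'
#' @return `stp_grid()`: a numeric vector of 240 times.
#'   `schedule_grid_2tp()`: a tibble with columns `t1`, `t2` (1770 rows).
#'   `schedule_grid_3tp()`: a tibble with columns `t1`, `t2`, `t3`
#'   (3294 rows). `valid_3tp_times()`: the 30 admissible daily-slot times.
#'   All enumerations are deterministic and lexicographically ordered.
#' @examples
#' nrow(schedule_grid_2tp())   # 1770
#' nrow(schedule_grid_3tp())   # 3294
#' @export
stp_grid <- function() {
  as.numeric(1:240)
}

#' @rdname stp_grid
#' @export
schedule_grid_2tp <- function() {
  times <- seq(4, 240, by = 4)
  idx <- utils::combn(length(times), 2)
  tibble::tibble(t1 = times[idx[1, ]], t2 = times[idx[2, ]]) |>
    dplyr::arrange(.data$t1, .data$t2)
}

#' @rdname stp_grid
#' @export
valid_3tp_times <- function() {
  slots <- sort(unique(c(4, 8, as.vector(outer(c(0, 4, 8), 24 * (1:9), "+")),
                         240)))
  as.numeric(slots)
}

#' @rdname stp_grid
#' @export
schedule_grid_3tp <- function() {
  times <- valid_3tp_times()
  idx <- utils::combn(length(times), 3)
  out <- tibble::tibble(t1 = times[idx[1, ]], t2 = times[idx[2, ]],
                        t3 = times[idx[3, ]])
  # no two scans on the same day: every pairwise gap must exceed 12 h
  out |>
    dplyr::filter(.data$t2 - .data$t1 > 12, .data$t3 - .data$t2 > 12) |>
    dplyr::arrange(.data$t1, .data$t2, .data$t3)
}

#' Clinical reduced-time-point combinations
#'
#' For a patient imaged `n_scans` times (the study design uses 4 sessions),
#' enumerates every subset of `r` scan indices used for reduced-time-point
#' refitting: 6 pairs and 4 triples for a 4-scan design. `r = n_scans` is
#' rejected — that is the reference fit itself, not a reduced schedule.
#'
#' @param n_scans Number of imaging sessions per patient (default 4).
#' @param r Number of time points retained (`2 <= r < n_scans`).
#' @return A tibble with one row per combination and columns `combo_id` and
#'   `idx` (list-column of integer index vectors).
#' @examples
#' clinical_combinations(4, 2)   # 6 rows
#' @export
clinical_combinations <- function(n_scans = 4, r) {
  if (length(r) != 1L || !is.finite(r) || r < 2 || r >= n_scans) {
    stop("`r` must satisfy 2 <= r < n_scans (r = n_scans is the reference).",
         call. = FALSE)
  }
  idx <- utils::combn(n_scans, r, simplify = FALSE)
  tibble::tibble(combo_id = seq_along(idx),
                 idx = lapply(idx, as.integer))
}

#' Scan time periods of the study design
#'
#' The four nominal imaging windows, in hours post-injection: day 0
#' (`t_D0`: 3-5 h), days 1-2 (`t_D1_2`: 21-52 h), days 3-5 (`t_D3_5`:
#' 71-126 h) and days 6-8 (`t_D6_8`: 144-194 h).
#'
#' @return A tibble with columns `label`, `low`, `high`.
#' @export
time_periods <- function() {
  tibble::tibble(
    label = c("t_D0", "t_D1_2", "t_D3_5", "t_D6_8"),
    low = c(3, 21, 71, 144),
    high = c(5, 52, 126, 194)
  )
}

#' Assign scan times to study time periods
#'
#' Times inside a window get that window's label. Real scheduling is
#' imperfect, so times falling between windows are assigned to the window
#' with the nearest boundary (and a warning is emitted) rather than dropped.
#'
#' @param t Scan times, hours post-injection (vectorised, `> 0`).
#' @param periods A [time_periods()]-shaped tibble.
#' @return A character vector of period labels.
#' @examples
#' assign_time_period(c(4, 24, 96, 168))
#' @export
assign_time_period <- function(t, periods = time_periods()) {
  if (any(t <= 0, na.rm = TRUE)) {
    stop("scan times must be > 0 h.", call. = FALSE)
  }
  labels <- character(length(t))
  out_of_window <- logical(length(t))
  for (i in seq_along(t)) {
    inside <- which(t[i] >= periods$low & t[i] <= periods$high)
    if (length(inside) > 0) {
      labels[i] <- periods$label[inside[1]]
    } else {
      dist <- pmin(abs(t[i] - periods$low), abs(t[i] - periods$high))
      labels[i] <- periods$label[which.min(dist)]
      out_of_window[i] <- TRUE
    }
  }
  if (any(out_of_window)) {
    warning(sum(out_of_window), " scan time(s) outside every nominal window; ",
            "assigned to the nearest window boundary.", call. = FALSE)
  }
  labels
}
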