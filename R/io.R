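#' Read and write time-activity tables
#'
#' The time-activity CSV schema is one row per measured sample:
#' `patient_id, structure, time_h, activity_MBq` (header mandatory, decimal
#' point, UTF-8). Extra columns are preserved. Schema violations abort with
#' a message naming the offending column or row.
#'
#' @param path File path.
#' @param data Data frame in the schema above.
#' @return `read_time_activity()`: a tibble. `write_time_activity()`: the
#'   input, invisibly.
#' @export
read_time_activity <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("patient_id", "structure", "time_h", "activity_MBq")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("time-activity file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$time_h) | df$time_h <= 0)
  if (length(bad) > 0) {
    stop("time-activity file ", path, ": non-positive or missing time_h at ",
         "data row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(df$activity_MBq) | df$activity_MBq < 0)
  if (length(bad) > 0) {
    stop("time-activity file ", path, ": negative or missing activity_MBq ",
         "at data row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_time_activity
#' @export
write_time_activity <- function(data, path) {
  req <- c("patient_id", "structure", "time_h", "activity_MBq")
  if (!all(req %in% names(data))) {
    stop("`data` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(data, path)
  invisible(data)
}

#' Read and write phantom repeat-measurement tables
#'
#' Schema: `object_label, scan_length_min, repeat_index, activity_MBq`.
#'
#' @inheritParams read_time_activity
#' @return `read_phantom_table()`: a tibble. `write_phantom_table()`: the
#'   input, invisibly.
#' @export
read_phantom_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("object_label", "scan_length_min", "repeat_index", "activity_MBq")
  missing <- setdiff(req, names(df))
  if (length(missing) > 0) {
    stop("phantom file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$scan_length_min) | df$scan_length_min <= 0)) {
    stop("phantom file ", path, ": scan_length_min must be > 0.",
         call. = FALSE)
  }
  df
}

#' @rdname read_phantom_table
#' @export
write_phantom_table <- function(data, path) {
  req <- c("object_label", "scan_length_min", "repeat_index", "activity_MBq")
  if (!all(req %in% names(data))) {
    stop("`data` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(data, path)
  invisible(data)
}

#' Read a run configuration (JSON or YAML)
#'
#' Accepted keys: `seed` (integer, required if any stochastic stage is on),
#' `population_kinetics` (map structure -> T_pop hours),
#' `noise` (`{a, b}`, a path to a phantom CSV, or `"off"`),
#' `schedules` (subset of stp/2tp/3tp), `n_curves`,
#' `invalid_policy` (`exclude`/`penalize`) and `cap_pct`.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A named list with class `run_config`; `population_kinetics` is
#'   returned as a [population_kinetics()] tibble and `noise` as a
#'   [noise_model()] (or `NULL` when off).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  cfg <- list(
    seed = raw$seed,
    n_curves = raw$n_curves %||% 250,
    schedules = raw$schedules %||% c("stp", "2tp", "3tp"),
    invalid_policy = raw$invalid_policy %||% "exclude",
    cap_pct = raw$cap_pct %||% 1000
  )
  if (!is.null(raw$population_kinetics)) {
    pk <- raw$population_kinetics
    cfg$population_kinetics <- population_kinetics(names(pk),
                                                   unlist(pk, use.names = FALSE))
  } else {
    cfg$population_kinetics <- default_population_kinetics()
  }
  # YAML 1.1 parses a bare `off` as FALSE; accept both spellings
  if (is.null(raw$noise) || identical(raw$noise, "off") ||
      isFALSE(raw$noise)) {
    cfg$noise <- NULL
  } else if (is.character(raw$noise)) {
    cfg$noise <- fit_noise_model(read_phantom_table(raw$noise))
  } else {
    cfg$noise <- noise_model(raw$noise$a, raw$noise$b)
  }
  if (is.null(cfg$seed)) {
    stop("config ", path, ": `seed` is required.", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Write sampling schedules as CSV
#'
#' One row per schedule with columns `t1_h`, `t2_h`, `t3_h`; unused slots
#' are left blank.
#'
#' @param schedules Tibble with columns among `t1`, `t2`, `t3`.
#' @param path Output path.
#' @return The written tibble, invisibly.
#' @export
write_schedules <- function(schedules, path) {
  out <- tibble::tibble(
    t1_h = schedules$t1,
    t2_h = if ("t2" %in% names(schedules)) schedules$t2 else NA_real_,
    t3_h = if ("t3" %in% names(schedules)) schedules$t3 else NA_real_
  )
  readr::write_csv(out, path, na = "")
  invisible(out)
}

#' Write simulation outputs with provenance
#'
#' Writes the per-schedule summary table as CSV (floats at 6 significant
#' digits, so identical runs are byte-identical) plus a JSON sidecar with
#' the seed, configuration hash and population kinetics used — no orphan
#' result files.
#'
#' @param sim A `tia_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "tia_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sum_path <- file.path(dir, "schedule_summaries.csv")
  meta_path <- file.path(dir, "run_metadata.json")
  out <- dplyr::mutate(sim$summaries, dplyr::across(
    dplyr::where(is.numeric), ~ signif(.x, 6)))
  readr::write_csv(out, sum_path, na = "")
  cfg <- sim$config
  cfg$population_kinetics <- as.list(stats::setNames(
    cfg$population_kinetics$T_pop_h, cfg$population_kinetics$structure))
  cfg$config_hash <- rlang::hash(cfg)
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), meta_path)
  invisible(c(summaries = sum_path, metadata = meta_path))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
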