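# ---- truncated lognormal parameter specs -----------------------------------

#' Truncated lognormal specification for one curve-fit parameter
#'
#' Parameterised the way the cohort statistics are derived: `s` is the
#' standard deviation of the natural log of the cohort values and `mu` is the
#' exponential of the mean of the natural log (the geometric mean), so the
#' underlying draw is `rlnorm(meanlog = log(mu), sdlog = s)`. Draws are
#' rejected until they fall inside `[lower, upper]`.
#'
#' @param s SD of the log values (`>= 0`).
#' @param mu Geometric mean of the values (`> 0`), in the parameter's units.
#' @param lower,upper Truncation bounds (`0 < lower <= mu <= upper`).
#' @return An object of class `lognormal_spec`.
#' @export
lognormal_spec <- function(s, mu, lower = mu * exp(-2.5 * max(s, 1e-12)),
                           upper = mu * exp(2.5 * max(s, 1e-12))) {
  if (!is.finite(s) || s < 0) stop("`s` must be finite and >= 0.", call. = FALSE)
  if (!is.finite(mu) || mu <= 0) stop("`mu` must be > 0.", call. = FALSE)
  if (!(lower > 0) || lower > mu || upper < mu) {
    stop("need 0 < lower <= mu <= upper.", call. = FALSE)
  }
  structure(list(s = s, mu = mu, lower = lower, upper = upper),
            class = "lognormal_spec")
}

# rejection sampling; cap guards misconfigured (near-empty) bounds
sample_lognormal_spec <- function(spec, n, max_attempts = 1e5) {
  if (spec$s == 0) return(rep(spec$mu, n))
  out <- numeric(0)
  attempts <- 0
  while (length(out) < n) {
    draw <- stats::rlnorm(n, meanlog = log(spec$mu), sdlog = spec$s)
    out <- c(out, draw[draw >= spec$lower & draw <= spec$upper])
    attempts <- attempts + n
    if (attempts > max_attempts) {
      stop("rejection sampling failed after ", max_attempts,
           " attempts; truncation bounds are inconsistent with (s, mu).",
           call. = FALSE)
    }
  }
  out[seq_len(n)]
}

# ---- cohort distributions --------------------------------------------------

spec_from_values <- function(vals) {
  if (any(vals <= 0)) {
    stop("cohort parameter values must be positive for a lognormal model.",
         call. = FALSE)
  }
  lv <- log(vals)
  # exp(mean(log(x))) can land an ulp outside [min, max] for identical values
  mu <- min(max(exp(mean(lv)), min(vals)), max(vals))
  lognormal_spec(s = stats::sd(lv), mu = mu,
                 lower = min(vals), upper = max(vals))
}

#' Derive per-structure parameter distributions from reference fits
#'
#' For every structure, collects the valid reference fits, records the
#' observed mono/bi fit-type labels (the bootstrap source), and fits a
#' truncated lognormal to each parameter of each fit family: `s` = SD of the
#' log values, `mu` = exp of the mean of the log values, truncation at the
#' cohort minimum and maximum. For the clearance constant (`lambda1` of a
#' mono fit, `lambda1` of a bi fit) a wider literature effective-half-life
#' range may be supplied per structure; any bound wider than the cohort's is
#' substituted (half-lives `[T_lo, T_hi]` in hours map to decay-constant
#' bounds `[log(2)/T_hi, log(2)/T_lo]`).
#'
#' A fit family with fewer than two fits in a structure is dropped from that
#' structure's bootstrap source.
#'
#' @param fits A tibble of reference fits as returned by [fit_tac()]
#'   (columns `structure`, `kind`, `C`, `lambda1`, `lambda2`, `valid`).
#' @param halflife_cutoffs Optional named list, `structure -> c(T_lo, T_hi)`
#'   hours, of literature effective-half-life ranges.
#' @return An object of class `cohort_distribution`: a named list with one
#'   entry per structure, each holding `fit_labels` and per-family
#'   [lognormal_spec()]s.
#' @export
derive_cohort_distribution <- function(fits, halflife_cutoffs = NULL) {
  req <- c("structure", "kind", "C", "lambda1", "lambda2", "valid")
  if (!is.data.frame(fits) || !all(req %in% names(fits))) {
    stop("`fits` needs columns structure, kind, C, lambda1, lambda2, valid.",
         call. = FALSE)
  }
  fits <- dplyr::filter(tibble::as_tibble(fits), .data$valid)
  if (nrow(fits) == 0) stop("no valid reference fits supplied.", call. = FALSE)

  widen_lambda <- function(spec, cuts) {
    if (is.null(cuts)) return(spec)
    lam_lo <- log(2) / cuts[2]
    lam_hi <- log(2) / cuts[1]
    lognormal_spec(s = spec$s, mu = spec$mu,
                   lower = min(spec$lower, lam_lo),
                   upper = max(spec$upper, lam_hi))
  }

  out <- lapply(split(fits, fits$structure), function(sf) {
    cuts <- halflife_cutoffs[[sf$structure[1]]]
    entry <- list(structure = sf$structure[1], fit_labels = character(0),
                  mono = NULL, bi = NULL)
    mono <- sf[sf$kind == "mono", ]
    if (nrow(mono) >= 2) {
      entry$mono <- list(C = spec_from_values(mono$C),
                         lambda1 = widen_lambda(spec_from_values(mono$lambda1),
                                                cuts))
      entry$fit_labels <- c(entry$fit_labels, mono$kind)
    }
    bi <- sf[sf$kind == "bi", ]
    if (nrow(bi) >= 2) {
      entry$bi <- list(C = spec_from_values(bi$C),
                       lambda1 = widen_lambda(spec_from_values(bi$lambda1),
                                              cuts),
                       lambda2 = spec_from_values(bi$lambda2))
      entry$fit_labels <- c(entry$fit_labels, bi$kind)
    }
    if (length(entry$fit_labels) == 0) {
      stop("structure '", sf$structure[1],
           "' has no fit family with >= 2 valid fits.", call. = FALSE)
    }
    entry
  })
  structure(out, class = "cohort_distribution")
}

#' @export
print.cohort_distribution <- function(x, ...) {
  cat("<cohort_distribution>", length(x), "structure(s)\n")
  for (e in x) {
    frac_bi <- mean(e$fit_labels == "bi")
    cat(sprintf("  %-14s n_labels = %d (bi fraction %.2f)\n",
                e$structure, length(e$fit_labels), frac_bi))
  }
  invisible(x)
}

#' Construct a cohort distribution directly from specs
#'
#' Assembles a [derive_cohort_distribution()]-shaped object from explicit
#' [lognormal_spec()]s — the entry point for fully synthetic populations
#' where no clinical cohort exists.
#'
#' @param structure Structure label.
#' @param fit_labels Character vector of `"mono"`/`"bi"` labels to bootstrap
#'   fit types from (its composition sets the bi fraction).
#' @param mono Named list with specs `C`, `lambda1` (or `NULL`).
#' @param bi Named list with specs `C`, `lambda1`, `lambda2` (or `NULL`).
#' @return A one-structure `cohort_distribution`.
#' @export
cohort_distribution <- function(structure, fit_labels, mono = NULL, bi = NULL) {
  if (length(fit_labels) == 0 || !all(fit_labels %in% c("mono", "bi"))) {
    stop("`fit_labels` must be a non-empty vector of 'mono'/'bi'.",
         call. = FALSE)
  }
  if (any(fit_labels == "mono") && is.null(mono)) {
    stop("mono labels present but no mono specs supplied.", call. = FALSE)
  }
  if (any(fit_labels == "bi") && is.null(bi)) {
    stop("bi labels present but no bi specs supplied.", call. = FALSE)
  }
  out <- list()
  out[[structure]] <- list(structure = structure, fit_labels = fit_labels,
                           mono = mono, bi = bi)
  class(out) <- "cohort_distribution"
  out
}

#' Merge cohort distributions
#'
#' @param ... `cohort_distribution` objects.
#' @return A combined `cohort_distribution`.
#' @export
c.cohort_distribution <- function(...) {
  parts <- list(...)
  out <- unlist(lapply(parts, unclass), recursive = FALSE)
  structure(out, class = "cohort_distribution")
}

#' Draw simulated TAC models from a cohort distribution
#'
#' For each draw the fit type is sampled uniformly with replacement from the
#' structure's observed labels (the bootstrap), then each parameter is drawn
#' from its truncated lognormal. For biexponential draws the pair
#' `(lambda1, lambda2)` is resampled *jointly* until `lambda2 > lambda1`, so
#' the marginals are not distorted by swapping. Uses R's global RNG.
#'
#' @param dist A `cohort_distribution`.
#' @param structure Structure label to draw for (must exist in `dist`).
#' @param n Number of models to draw.
#' @param max_attempts Rejection cap for the ordering constraint.
#' @return A tibble with columns `kind`, `C`, `lambda1`, `lambda2`, `tia`.
#' @export
sample_tac <- function(dist, structure, n = 1, max_attempts = 1e5) {
  stopifnot(inherits(dist, "cohort_distribution"))
  e <- dist[[structure]]
  if (is.null(e)) {
    stop("structure '", structure, "' not present in the distribution.",
         call. = FALSE)
  }
  kind <- sample(e$fit_labels, n, replace = TRUE)
  C <- numeric(n); l1 <- numeric(n); l2 <- rep(NA_real_, n)
  n_mono <- sum(kind == "mono")
  if (n_mono > 0) {
    C[kind == "mono"] <- sample_lognormal_spec(e$mono$C, n_mono)
    l1[kind == "mono"] <- sample_lognormal_spec(e$mono$lambda1, n_mono)
  }
  n_bi <- sum(kind == "bi")
  if (n_bi > 0) {
    C[kind == "bi"] <- sample_lognormal_spec(e$bi$C, n_bi)
    a1 <- sample_lognormal_spec(e$bi$lambda1, n_bi)
    a2 <- sample_lognormal_spec(e$bi$lambda2, n_bi)
    bad <- a2 <= a1
    attempts <- 0
    while (any(bad)) {
      a1[bad] <- sample_lognormal_spec(e$bi$lambda1, sum(bad))
      a2[bad] <- sample_lognormal_spec(e$bi$lambda2, sum(bad))
      bad <- a2 <= a1
      attempts <- attempts + 1
      if (attempts > max_attempts) {
        stop("could not draw lambda2 > lambda1 within the attempt cap; ",
             "check the biexponential specs.", call. = FALSE)
      }
    }
    l1[kind == "bi"] <- a1
    l2[kind == "bi"] <- a2
  }
  tibble::tibble(kind = kind, C = C, lambda1 = l1, lambda2 = l2,
                 tia = analytic_tia_params(kind, C, l1, l2))
}

# ---- simulation study ------------------------------------------------------

# deterministic sub-seed derivation (kept below 2^31) so each
# (structure, stage) consumes an independent, reproducible stream
derive_seed <- function(seed, i, stage) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 + stage * 131071) %%
               2147483629)
}

#' Run the virtual-patient simulation study
#'
#' For each structure, draws `n_curves` ground-truth TAC models from the
#' cohort distribution, samples their activity on the hourly 1-240 h grid,
#' adds measurement noise (one noisy realisation per curve and grid time,
#' shared by every schedule that uses that time), and evaluates:
#' single-time-point estimators (Hanscheid and Madsen) at every hour of the
#' STP grid, exact two-point monoexponential refits for all 1770 schedule
#' pairs, and least-squares monoexponential refits for all 3294 admissible
#' triples. Estimates are scored against each curve's analytic TIA and
#' summarised per schedule with [summarize_tia_errors()].
#'
#' RNG is hierarchical: the global `seed` spawns one sub-stream per
#' (structure, stage), so adding or removing schedule families does not
#' perturb curve generation.
#'
#' @param dists A `cohort_distribution` covering the structures to simulate.
#' @param n_curves Simulated curves per structure (default 250).
#' @param noise A [noise_model()], or `NULL` to disable measurement noise.
#' @param schedules Character subset of `c("stp", "2tp", "3tp")`.
#' @param pop A [population_kinetics()] table for the Madsen estimator.
#' @param seed Integer seed governing all randomness.
#' @param keep_records If `TRUE`, retain the per-curve estimate records
#'   (large) in addition to the per-schedule summaries.
#' @param invalid_policy Passed to [summarize_tia_errors()]: `"exclude"`
#'   drops invalid fits from the metrics (they still count in `n_total`);
#'   `"penalize"` scores them at `cap_pct`.
#' @param cap_pct Percent-error cap used by the `"penalize"` policy.
#' @return An object of class `tia_simulation` with elements `summaries`
#'   (one row per structure x method x schedule), `truth` (the generating
#'   models), `config`, and optionally `records`.
#' @export
run_simulation_study <- function(dists, n_curves = 250, noise = NULL,
                                 schedules = c("stp", "2tp", "3tp"),
                                 pop = default_population_kinetics(),
                                 seed = 1, keep_records = FALSE,
                                 invalid_policy = c("exclude", "penalize"),
                                 cap_pct = 1000) {
  stopifnot(inherits(dists, "cohort_distribution"))
  invalid_policy <- match.arg(invalid_policy)
  schedules <- match.arg(schedules, several.ok = TRUE)
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_model"))

  grid <- stp_grid()
  pairs <- schedule_grid_2tp()
  triples <- schedule_grid_3tp()
  structures <- names(dists)

  all_sum <- list()
  all_truth <- list()
  all_rec <- list()

  for (i in seq_along(structures)) {
    st <- structures[i]

    set.seed(derive_seed(seed, i, 1L))
    truth <- sample_tac(dists, st, n_curves)
    all_truth[[st]] <- dplyr::mutate(truth, structure = st,
                                     curve_id = dplyr::row_number(),
                                     .before = 1)

    # activity on the hourly grid; noisy realisation shared across schedules
    e1 <- exp(-outer(truth$lambda1, grid))
    a_true <- truth$C * e1
    is_bi <- truth$kind == "bi"
    if (any(is_bi)) {
      a_true[is_bi, ] <- truth$C[is_bi] *
        (e1[is_bi, , drop = FALSE] - exp(-outer(truth$lambda2[is_bi], grid)))
    }
    a_true <- pmax(a_true, 0)
    if (!is.null(noise)) {
      set.seed(derive_seed(seed, i, 2L))
      a_obs <- matrix(apply_noise(as.vector(a_true), noise),
                      nrow = n_curves)
    } else {
      a_obs <- a_true
    }

    tia_true <- truth$tia
    rec_st <- list()

    if ("stp" %in% schedules) {
      lam_pop <- pop$lambda_pop[match(st, pop$structure)]
      if (is.na(lam_pop)) {
        stop("no population kinetics configured for structure '", st, "'.",
             call. = FALSE)
      }
      est_h <- sweep(a_obs, 2, 2 * grid / log(2), "*")
      est_m <- sweep(a_obs, 2, exp(lam_pop * grid) / lam_pop, "*")
      rec_st$hanscheid <- tibble::tibble(
        structure = st, method = "hanscheid",
        curve_id = rep(seq_len(n_curves), times = length(grid)),
        t1 = rep(grid, each = n_curves), t2 = NA_real_, t3 = NA_real_,
        tia_true = rep(tia_true, times = length(grid)),
        tia_est = as.vector(est_h),
        valid = as.vector(a_obs) > 0
      )
      rec_st$madsen <- tibble::tibble(
        structure = st, method = "madsen",
        curve_id = rep(seq_len(n_curves), times = length(grid)),
        t1 = rep(grid, each = n_curves), t2 = NA_real_, t3 = NA_real_,
        tia_true = rep(tia_true, times = length(grid)),
        tia_est = as.vector(est_m),
        valid = as.vector(a_obs) > 0
      )
    }

    if ("2tp" %in% schedules) {
      # hourly grid index of time t is simply t
      a1 <- a_obs[, pairs$t1, drop = FALSE]
      a2 <- a_obs[, pairs$t2, drop = FALSE]
      dt <- rep(pairs$t2 - pairs$t1, each = n_curves)
      t1r <- rep(pairs$t1, each = n_curves)
      ok_act <- a1 > 0 & a2 > 0
      lam <- matrix(NA_real_, n_curves, nrow(pairs))
      lam[ok_act] <- (log(a1[ok_act]) - log(a2[ok_act])) / dt[ok_act]
      Cp <- a1 * exp(lam * t1r)
      est <- Cp / lam
      valid <- ok_act & !is.na(lam) & lam > 0
      est[!valid] <- NA_real_
      rec_st$tp2 <- tibble::tibble(
        structure = st, method = "2tp",
        curve_id = rep(seq_len(n_curves), times = nrow(pairs)),
        t1 = rep(pairs$t1, each = n_curves),
        t2 = rep(pairs$t2, each = n_curves), t3 = NA_real_,
        tia_true = rep(tia_true, times = nrow(pairs)),
        tia_est = as.vector(est),
        valid = as.vector(valid)
      )
    }

    if ("3tp" %in% schedules) {
      nsch <- nrow(triples)
      tmat <- cbind(rep(triples$t1, each = n_curves),
                    rep(triples$t2, each = n_curves),
                    rep(triples$t3, each = n_curves))
      amat <- cbind(as.vector(a_obs[, triples$t1, drop = FALSE]),
                    as.vector(a_obs[, triples$t2, drop = FALSE]),
                    as.vector(a_obs[, triples$t3, drop = FALSE]))
      fit <- mono_fit_batch(tmat, amat)
      valid <- fit$lambda > 0 & fit$C > 0
      est <- ifelse(valid, fit$C / fit$lambda, NA_real_)
      rec_st$tp3 <- tibble::tibble(
        structure = st, method = "3tp",
        curve_id = rep(seq_len(n_curves), times = nsch),
        t1 = tmat[, 1], t2 = tmat[, 2], t3 = tmat[, 3],
        tia_true = rep(tia_true, times = nsch),
        tia_est = est,
        valid = valid
      )
    }

    rec_st <- dplyr::bind_rows(rec_st)
    all_sum[[st]] <- rec_st |>
      dplyr::group_by(.data$structure, .data$method, .data$t1, .data$t2,
                      .data$t3) |>
      summarize_tia_errors(policy = invalid_policy, cap_pct = cap_pct)
    if (keep_records) all_rec[[st]] <- rec_st
  }

  structure(
    list(
      summaries = dplyr::bind_rows(all_sum),
      truth = dplyr::bind_rows(all_truth),
      config = list(seed = seed, n_curves = n_curves,
                    noise = if (is.null(noise)) NULL else
                      list(a = noise$a, b = noise$b),
                    schedules = schedules,
                    population_kinetics = pop,
                    invalid_policy = invalid_policy, cap_pct = cap_pct),
      records = if (keep_records) dplyr::bind_rows(all_rec) else NULL
    ),
    class = "tia_simulation"
  )
}

#' @export
print.tia_simulation <- function(x, ...) {
  cat("<tia_simulation>\n")
  cat("  structures:", paste(unique(x$summaries$structure), collapse = ", "),
      "\n")
  cat("  curves per structure:", x$config$n_curves,
      "| seed:", x$config$seed, "\n")
  if (is.null(x$config$noise)) {
    cat("  measurement noise: off\n")
  } else {
    cat(sprintf("  measurement noise: RSD(A) = %.4g * A^%.4g\n",
                x$config$noise$a, x$config$noise$b))
  }
  cat("  schedule summaries:", nrow(x$summaries), "rows\n")
  invisible(x)
}

#' Serialise a cohort distribution to JSON
#'
#' Writes the shareable "population prior": per structure, the fit-type
#' labels and each parameter's `(s, mu, lower, upper)`.
#'
#' @param dist A `cohort_distribution`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @param json JSON text or a file path to read from.
#' @return `cohort_distribution_to_json()`: JSON string (invisibly if
#'   written to a file); `cohort_distribution_from_json()`: the object.
#' @export
cohort_distribution_to_json <- function(dist, path = NULL) {
  stopifnot(inherits(dist, "cohort_distribution"))
  payload <- lapply(unclass(dist), function(e) {
    spec_rec <- function(sp) {
      if (is.null(sp)) return(NULL)
      lapply(sp, function(p) list(s = p$s, mu = p$mu, lower = p$lower,
                                  upper = p$upper))
    }
    list(structure = e$structure, fit_labels = e$fit_labels,
         mono = spec_rec(e$mono), bi = spec_rec(e$bi))
  })
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname cohort_distribution_to_json
#' @export
cohort_distribution_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  out <- lapply(payload, function(e) {
    mk <- function(sp) {
      if (is.null(sp)) return(NULL)
      lapply(sp, function(p) lognormal_spec(p$s, p$mu, p$lower, p$upper))
    }
    list(structure = e$structure,
         fit_labels = unlist(e$fit_labels),
         mono = mk(e$mono), bi = mk(e$bi))
  })
  names(out) <- vapply(out, function(e) e$structure, character(1))
  structure(out, class = "cohort_distribution")
}
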