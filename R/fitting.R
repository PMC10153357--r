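# ---- internal: profiled monoexponential least squares ----------------------
#
# For fixed lambda the optimal amplitude is linear:
#   C(lambda) = sum(A f) / sum(f^2),  f = exp(-lambda t)
# so the fit reduces to 1-D minimisation of the profiled RSS over lambda.
# The batch version solves many (t, A) problems at once (grid search over a
# fixed lambda grid followed by vectorised golden-section refinement); it is
# what the simulator uses for the hundreds of thousands of 3TP refits, and
# fit_mono_lsq() routes single problems through the same code path.

.mono_lambda_grid <- function() {
  # negative branch lets noise-driven rising curves settle on lambda < 0
  # (returned flagged invalid downstream); positive branch spans effective
  # half-lives from ~0.5 h to ~7000 h
  c(seq(-0.08, -1e-4, length.out = 8), 1e-4 * (1.5 / 1e-4)^(seq(0, 1, length.out = 48)))
}

# tmat, amat: n_problems x n_points matrices. Returns list(lambda, C, rss).
mono_fit_batch <- function(tmat, amat, n_refine = 48L) {
  stopifnot(is.matrix(tmat), is.matrix(amat), all(dim(tmat) == dim(amat)))
  np <- nrow(tmat)
  a2 <- rowSums(amat^2)

  rss_at <- function(lam) {
    f <- exp(-lam * tmat)
    # amplitude constrained positive: negative profile C collapses to C = 0
    C <- pmax(rowSums(amat * f), 0) / rowSums(f * f)
    rowSums((amat - C * f)^2)
  }

  grid <- .mono_lambda_grid()
  best_rss <- rep(Inf, np)
  best_idx <- rep(1L, np)
  for (i in seq_along(grid)) {
    r <- rss_at(grid[i])
    upd <- r < best_rss
    best_rss[upd] <- r[upd]
    best_idx[upd] <- i
  }
  lo <- grid[pmax(best_idx - 1L, 1L)]
  hi <- grid[pmin(best_idx + 1L, length(grid))]

  # vectorised golden-section on per-problem brackets
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- rss_vec_at(x1, tmat, amat, a2)
  f2 <- rss_vec_at(x2, tmat, amat, a2)
  for (k in seq_len(n_refine)) {
    move_right <- f1 > f2
    lo[move_right] <- x1[move_right]
    hi[!move_right] <- x2[!move_right]
    x1 <- hi - gr * (hi - lo)
    x2 <- lo + gr * (hi - lo)
    f1 <- rss_vec_at(x1, tmat, amat, a2)
    f2 <- rss_vec_at(x2, tmat, amat, a2)
  }
  lambda <- (lo + hi) / 2
  f <- exp(-lambda * tmat)
  C <- pmax(rowSums(amat * f), 0) / rowSums(f * f)
  # residual-space RSS: the profiled shortcut a2 - C^2 * S2 cancels
  # catastrophically near exact fits
  rss <- rowSums((amat - C * f)^2)
  list(lambda = lambda, C = C, rss = rss)
}

# evaluate the profiled RSS at a *vector* of lambdas (one per problem);
# residual-space evaluation keeps near-exact fits free of cancellation noise
rss_vec_at <- function(lam, tmat, amat, a2) {
  f <- exp(-lam * tmat)
  C <- pmax(rowSums(amat * f), 0) / rowSums(f * f)
  rowSums((amat - C * f)^2)
}

# ---- tac_fit objects -------------------------------------------------------

new_tac_fit <- function(kind, C, lambda1, lambda2, rss, n_points, k_params,
                        valid, method, diagnostic = NA_character_) {
  rss_floor <- 1e-12
  aic <- n_points * log(max(rss, rss_floor) / n_points) + 2 * k_params
  tia <- if (valid) analytic_tia_params(kind, C, lambda1, lambda2) else NA_real_
  structure(
    list(kind = kind, C = C, lambda1 = lambda1, lambda2 = lambda2,
         rss = rss, aic = aic, n_points = as.integer(n_points),
         k_params = as.integer(k_params), tia = tia, valid = valid,
         method = method, diagnostic = diagnostic),
    class = "tac_fit"
  )
}

#' @export
print.tac_fit <- function(x, ...) {
  cat(sprintf("<tac_fit> %s (%s), n = %d, valid = %s\n",
              x$kind, x$method, x$n_points, x$valid))
  if (x$kind == "mono") {
    cat(sprintf("  C = %.6g MBq, lambda = %.6g /h", x$C, x$lambda1))
  } else {
    cat(sprintf("  C = %.6g MBq, lambda1 = %.6g /h, lambda2 = %.6g /h",
                x$C, x$lambda1, x$lambda2))
  }
  cat(sprintf("\n  rss = %.4g MBq^2, AIC = %.4g, TIA = %.6g MBq h\n",
              x$rss, x$aic, x$tia))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TAC fit
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row model-level summary (parameters, RSS, AIC, TIA, validity).
#'
#' @param x A `tac_fit` as returned by [fit_mono_lsq()] and friends.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tac_fit
#' @export
tidy.tac_fit <- function(x, ...) {
  terms <- if (x$kind == "mono") c("C", "lambda") else c("C", "lambda1", "lambda2")
  est <- if (x$kind == "mono") c(x$C, x$lambda1) else c(x$C, x$lambda1, x$lambda2)
  tibble::tibble(term = terms, estimate = est)
}

#' @rdname tidy.tac_fit
#' @method glance tac_fit
#' @export
glance.tac_fit <- function(x, ...) {
  tibble::tibble(kind = x$kind, C = x$C, lambda1 = x$lambda1,
                 lambda2 = x$lambda2, rss = x$rss, aic = x$aic,
                 n_points = x$n_points, tia = x$tia, valid = x$valid,
                 method = x$method)
}

check_samples <- function(samples, n_min) {
  if (!is.data.frame(samples) ||
      !all(c("time_h", "activity_MBq") %in% names(samples))) {
    stop("`samples` must be a data frame with columns time_h and activity_MBq.",
         call. = FALSE)
  }
  if (nrow(samples) < n_min) {
    stop(sprintf("at least %d samples are required.", n_min), call. = FALSE)
  }
  if (any(samples$time_h <= 0) || any(!is.finite(samples$time_h))) {
    stop("sample times must be finite and > 0 h.", call. = FALSE)
  }
  if (any(samples$activity_MBq < 0) || any(!is.finite(samples$activity_MBq))) {
    stop("activities must be finite and >= 0 MBq.", call. = FALSE)
  }
  samples[order(samples$time_h), , drop = FALSE]
}

#' Exact two-point monoexponential fit
#'
#' Inverts a monoexponential through two samples exactly:
#' \eqn{\lambda = \ln(A_1/A_2)/(t_2 - t_1)}, \eqn{C = A_1 e^{\lambda t_1}}.
#' Equal or rising activities give a non-positive decay constant; the fit is
#' then returned *flagged invalid* (with `tia = NA`) rather than raising, so
#' cohort error analysis can count such schedules as failures.
#'
#' @param samples Data frame with columns `time_h`, `activity_MBq` and
#'   exactly two rows (distinct times, both activities positive).
#' @return A `tac_fit`.
#' @examples
#' fit_mono_2tp(data.frame(time_h = c(24, 48), activity_MBq = c(50, 25)))
#' @export
fit_mono_2tp <- function(samples) {
  samples <- check_samples(samples, 2L)
  if (nrow(samples) != 2L) stop("exactly 2 samples are required.", call. = FALSE)
  t <- samples$time_h; a <- samples$activity_MBq
  if (any(a <= 0)) {
    stop("two-point inversion needs strictly positive activities.",
         call. = FALSE)
  }
  lambda <- log(a[1] / a[2]) / (t[2] - t[1])
  C <- a[1] * exp(lambda * t[1])
  new_tac_fit("mono", C = C, lambda1 = lambda, lambda2 = NA_real_, rss = 0,
              n_points = 2L, k_params = 2L, valid = lambda > 0,
              method = "mono_2tp",
              diagnostic = if (lambda > 0) NA_character_ else
                "non-positive decay constant (flat or rising activity)")
}

#' Monoexponential least-squares fit
#'
#' Minimises \eqn{\sum_i (A_i - C e^{-\lambda t_i})^2} over \eqn{C > 0} with
#' \eqn{\lambda} unconstrained in sign. Residuals are taken in activity space
#' (unweighted); the amplitude is profiled out in closed form and the
#' resulting 1-D problem solved by a deterministic grid search plus
#' golden-section refinement, which covers (and is insensitive to) the usual
#' log-linear initialisation. Fits with \eqn{\lambda \le 0} are returned
#' flagged invalid.
#'
#' @inheritParams fit_mono_2tp
#' @param samples Data frame with `time_h`, `activity_MBq`; at least 2 rows,
#'   at least 2 of them with positive activity.
#' @return A `tac_fit`.
#' @export
fit_mono_lsq <- function(samples) {
  samples <- check_samples(samples, 2L)
  if (sum(samples$activity_MBq > 0) < 2L) {
    stop("at least 2 positive activities are required for a mono fit.",
         call. = FALSE)
  }
  res <- mono_fit_batch(matrix(samples$time_h, nrow = 1),
                        matrix(samples$activity_MBq, nrow = 1))
  lambda <- res$lambda[1]; C <- res$C[1]
  valid <- lambda > 0 && C > 0
  new_tac_fit("mono", C = C, lambda1 = lambda, lambda2 = NA_real_,
              rss = res$rss[1], n_points = nrow(samples), k_params = 2L,
              valid = valid, method = "mono_lsq",
              diagnostic = if (valid) NA_character_ else
                "non-positive decay constant or amplitude")
}

#' Biexponential least-squares fit
#'
#' Fits \eqn{A(t) = C (e^{-\lambda_1 t} - e^{-\lambda_2 t})} by unweighted
#' activity-space least squares subject to \eqn{C > 0},
#' \eqn{\lambda_2 > \lambda_1 > 0}. The amplitude is profiled out in closed
#' form; \eqn{(\log \lambda_1, \log(\lambda_2 - \lambda_1))} is optimised by
#' Nelder-Mead from a fixed multi-start grid (\eqn{\lambda_1} starting at
#' \eqn{\ln 2 / \{200, 100, 50\}} per hour and \eqn{\lambda_2 = m \lambda_1},
#' \eqn{m \in \{3, 10\}}); the lowest-RSS start is kept. The start grid is
#' fixed and seed-free, so the fit is deterministic.
#'
#' At least 4 samples are required: with 3 free parameters, 3-point data is
#' underconstrained.
#'
#' @inheritParams fit_mono_2tp
#' @return A `tac_fit`.
#' @export
fit_bi_lsq <- function(samples) {
  samples <- check_samples(samples, 4L)
  t <- samples$time_h; a <- samples$activity_MBq

  profile_rss <- function(par) {
    l1 <- exp(par[1]); l2 <- l1 + exp(par[2])
    f <- exp(-l1 * t) - exp(-l2 * t)
    s2 <- sum(f * f)
    if (s2 <= 0 || !is.finite(s2)) return(sum(a^2))
    C <- max(sum(a * f), 0) / s2
    sum((a - C * f)^2)
  }

  l1_starts <- log(2) / c(200, 100, 50)
  best <- NULL
  for (l1 in l1_starts) {
    for (m in c(3, 10)) {
      par0 <- c(log(l1), log((m - 1) * l1))
      opt <- stats::optim(par0, profile_rss, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14))
      # polish: restart once from the optimum (Nelder-Mead can stall)
      opt <- stats::optim(opt$par, profile_rss, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  l1 <- exp(best$par[1]); l2 <- l1 + exp(best$par[2])
  f <- exp(-l1 * t) - exp(-l2 * t)
  C <- max(sum(a * f), 0) / sum(f * f)
  valid <- is.finite(C) && C > 0 && l2 > l1 && l1 > 0
  new_tac_fit("bi", C = C, lambda1 = l1, lambda2 = l2,
              rss = max(best$value, 0), n_points = nrow(samples),
              k_params = 3L, valid = valid, method = "bi_lsq",
              diagnostic = if (valid) NA_character_ else
                "no admissible biexponential optimum found")
}

#' AIC model selection for the four-point reference fit
#'
#' Fits both the monoexponential (2 parameters) and the biexponential
#' (3 parameters) to exactly four samples and returns the fit with the lower
#' Akaike information criterion, \eqn{AIC = n \ln(RSS/n) + 2k} (RSS floored
#' at \eqn{10^{-12}} MBq\eqn{^2} to guard \eqn{\ln 0}). Ties, or both fits at
#' the RSS floor, resolve to the monoexponential (parsimony). Plain AIC is
#' used rather than AICc: with n = 4 and k = 3 the AICc correction divides by
#' zero.
#'
#' @inheritParams fit_mono_2tp
#' @param samples Data frame with `time_h`, `activity_MBq`; exactly 4 rows.
#' @return The selected `tac_fit`.
#' @export
select_model_aic <- function(samples) {
  samples <- check_samples(samples, 4L)
  if (nrow(samples) != 4L) {
    stop("the reference fit uses exactly 4 samples.", call. = FALSE)
  }
  fm <- fit_mono_lsq(samples)
  fb <- fit_bi_lsq(samples)
  if (!fm$valid && !fb$valid) {
    stop("no valid reference fit: both mono and bi candidates are inadmissible.",
         call. = FALSE)
  }
  if (!fb$valid) return(fm)
  if (!fm$valid) return(fb)
  rss_floor <- 1e-12
  if (fm$rss <= rss_floor && fb$rss <= rss_floor) return(fm)
  if (fm$aic <= fb$aic) fm else fb
}

#' Fit reference models across a cohort
#'
#' Applies [select_model_aic()] (or a fixed fit family) to every
#' `(patient_id, structure)` curve in a long time-activity table and returns
#' one row per curve in the broom `glance()` layout. Curves whose reference
#' fit fails are returned with `valid = FALSE` rather than aborting the
#' cohort.
#'
#' @param data Data frame with columns `patient_id`, `structure`, `time_h`,
#'   `activity_MBq`.
#' @param method `"auto"` (AIC selection, 4-point curves), `"mono"`
#'   (least-squares mono), or `"bi"`.
#' @return A tibble with columns `patient_id`, `structure`, `kind`, `C`,
#'   `lambda1`, `lambda2`, `rss`, `aic`, `n_points`, `tia`, `valid`, `method`.
#' @export
fit_tac <- function(data, method = c("auto", "mono", "bi")) {
  method <- match.arg(method)
  req <- c("patient_id", "structure", "time_h", "activity_MBq")
  if (!is.data.frame(data) || !all(req %in% names(data))) {
    stop("`data` needs columns patient_id, structure, time_h, activity_MBq.",
         call. = FALSE)
  }
  fitter <- switch(method,
                   auto = select_model_aic,
                   mono = fit_mono_lsq,
                   bi = fit_bi_lsq)
  data |>
    dplyr::group_by(.data$patient_id, .data$structure) |>
    tidyr::nest(samples = c("time_h", "activity_MBq")) |>
    dplyr::ungroup() |>
    dplyr::mutate(fit = purrr::map(.data$samples, function(s) {
      tryCatch(glance(fitter(s)),
               error = function(e) tibble::tibble(
                 kind = NA_character_, C = NA_real_, lambda1 = NA_real_,
                 lambda2 = NA_real_, rss = NA_real_, aic = NA_real_,
                 n_points = nrow(s), tia = NA_real_, valid = FALSE,
                 method = method))
    })) |>
    dplyr::select(-"samples") |>
    tidyr::unnest("fit")
}
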