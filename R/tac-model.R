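#' Exponential time-activity curve model
#'
#' Constructs a mono- or biexponential time-activity curve (TAC) model of the
#' form \eqn{A(t) = C e^{-\lambda t}} (mono) or
#' \eqn{A(t) = C (e^{-\lambda_1 t} - e^{-\lambda_2 t})} (bi). Decay constants
#' are *effective* decay constants (biological clearance plus physical decay)
#' in 1/h; `C` is an amplitude in MBq.
#'
#' For the biexponential form `lambda2 > lambda1 > 0` is required strictly:
#' equal constants collapse the curve to zero everywhere, and the ordering
#' guarantees non-negative activity for `t >= 0` and a finite positive
#' time-integrated activity.
#'
#' @param kind `"mono"` or `"bi"`.
#' @param C Amplitude, MBq. Must be positive.
#' @param lambda1 Effective decay constant, 1/h. The single decay constant
#'   for `kind = "mono"`; the slow (clearance) constant for `kind = "bi"`.
#' @param lambda2 Fast (uptake) decay constant, 1/h; required iff
#'   `kind = "bi"` and must exceed `lambda1`.
#' @return An object of class `tac_model`.
#' @examples
#' m <- tac_model("mono", C = 100, lambda1 = log(2) / 50)
#' eval_activity(m, c(4, 24, 96, 168))
#' analytic_tia(m)
#' @export
tac_model <- function(kind = c("mono", "bi"), C, lambda1, lambda2 = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(C) || length(C) != 1L || !is.finite(C) || C <= 0) {
    stop("`C` must be a single positive finite number (MBq).", call. = FALSE)
  }
  if (!is.numeric(lambda1) || length(lambda1) != 1L || !is.finite(lambda1) ||
      lambda1 <= 0) {
    stop("`lambda1` must be a single positive finite number (1/h).",
         call. = FALSE)
  }
  if (kind == "bi") {
    if (is.null(lambda2) || !is.numeric(lambda2) || length(lambda2) != 1L ||
        !is.finite(lambda2)) {
      stop("biexponential models require a finite `lambda2`.", call. = FALSE)
    }
    if (lambda2 <= lambda1) {
      stop("biexponential models require `lambda2 > lambda1` (strictly).",
           call. = FALSE)
    }
  } else {
    if (!is.null(lambda2) && !is.na(lambda2)) {
      stop("`lambda2` must be absent for monoexponential models.",
           call. = FALSE)
    }
    lambda2 <- NA_real_
  }
  structure(
    list(kind = kind, C = as.numeric(C), lambda1 = as.numeric(lambda1),
         lambda2 = as.numeric(lambda2)),
    class = "tac_model"
  )
}

#' @export
print.tac_model <- function(x, ...) {
  if (x$kind == "mono") {
    cat(sprintf("<tac_model: mono> A(t) = %.6g * exp(-%.6g t)   [T_eff = %.4g h]\n",
                x$C, x$lambda1, log(2) / x$lambda1))
  } else {
    cat(sprintf(
      "<tac_model: bi>   A(t) = %.6g * (exp(-%.6g t) - exp(-%.6g t))\n",
      x$C, x$lambda1, x$lambda2))
  }
  cat(sprintf("  analytic TIA = %.6g MBq h\n", analytic_tia(x)))
  invisible(x)
}

# vectorised activity evaluation over parallel parameter vectors; the
# workhorse behind eval_activity() and the simulator. All arguments recycle
# to the longest length (a scalar model with a vector of times, or parallel
# model vectors with one time each).
eval_activity_params <- function(kind, C, lambda1, lambda2, t) {
  n <- max(length(kind), length(C), length(t))
  kind <- rep_len(kind, n); C <- rep_len(C, n); t <- rep_len(t, n)
  lambda1 <- rep_len(lambda1, n); lambda2 <- rep_len(lambda2, n)
  out <- C * exp(-lambda1 * t)
  bi <- kind == "bi"
  out[bi] <- C[bi] * (exp(-lambda1[bi] * t[bi]) - exp(-lambda2[bi] * t[bi]))
  # clamp the tiny negative round-off a biexponential difference can produce
  pmax(out, 0)
}

#' Evaluate a TAC model's activity at given times
#'
#' @param model A [tac_model()].
#' @param t Times in hours post-injection (vectorised, all `>= 0`).
#' @return Activity in MBq, same length as `t`; always `>= 0`.
#' @export
eval_activity <- function(model, t) {
  stopifnot(inherits(model, "tac_model"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0 (hours post-injection).", call. = FALSE)
  }
  eval_activity_params(model$kind, model$C, model$lambda1, model$lambda2, t)
}

# vectorised analytic TIA over parallel parameter vectors (NA-safe for mono)
analytic_tia_params <- function(kind, C, lambda1, lambda2) {
  ifelse(kind == "mono", C / lambda1, C * (1 / lambda1 - 1 / lambda2))
}

#' Analytic time-integrated activity
#'
#' Integrates the model activity over \eqn{[0, \infty)} in closed form:
#' \eqn{C/\lambda} for a monoexponential and
#' \eqn{C (1/\lambda_1 - 1/\lambda_2)} for a biexponential. This is the
#' ground-truth TIA against which reduced-time-point estimates are scored.
#'
#' @param model A [tac_model()] or a data frame with columns `kind`, `C`,
#'   `lambda1`, `lambda2` (one model per row).
#' @return For a `tac_model`, a positive scalar in MBq h. For a data frame,
#'   the input as a tibble with a `tia` column appended.
#' @export
analytic_tia <- function(model) {
  if (inherits(model, "tac_model")) {
    return(analytic_tia_params(model$kind, model$C, model$lambda1,
                               model$lambda2))
  }
  if (is.data.frame(model)) {
    req <- c("kind", "C", "lambda1", "lambda2")
    if (!all(req %in% names(model))) {
      stop("data-frame input needs columns kind, C, lambda1, lambda2.",
           call. = FALSE)
    }
    return(dplyr::mutate(
      tibble::as_tibble(model),
      tia = analytic_tia_params(.data$kind, .data$C, .data$lambda1,
                                .data$lambda2)
    ))
  }
  stop("`model` must be a tac_model or a data frame of model parameters.",
       call. = FALSE)
}

#' Serialise / deserialise TAC models as JSON records
#'
#' The JSON schema is `{kind, C_MBq, lambda1_per_h, lambda2_per_h?}` with
#' `lambda2_per_h` present only for biexponential models.
#'
#' @param model A [tac_model()].
#' @param json A JSON string produced by `tac_model_to_json()`.
#' @return `tac_model_to_json()` returns a JSON string;
#'   `tac_model_from_json()` returns a [tac_model()].
#' @export
tac_model_to_json <- function(model) {
  stopifnot(inherits(model, "tac_model"))
  rec <- list(kind = model$kind, C_MBq = model$C,
              lambda1_per_h = model$lambda1)
  if (model$kind == "bi") rec$lambda2_per_h <- model$lambda2
  jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
}

#' @rdname tac_model_to_json
#' @export
tac_model_from_json <- function(json) {
  rec <- jsonlite::fromJSON(json)
  tac_model(rec$kind, C = rec$C_MBq, lambda1 = rec$lambda1_per_h,
            lambda2 = rec$lambda2_per_h)
}
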