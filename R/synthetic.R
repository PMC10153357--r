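#' Configuration for a synthetic clinical-like cohort
#'
#' Describes a virtual patient cohort emulating a four-session post-therapy
#' imaging study: `n_patients` patients (default 28), each with a healthy
#' liver, left and right kidney, spleen, and 1-5 index tumors, imaged once
#' inside each of the four nominal windows (3-5, 21-52, 71-126 and
#' 144-194 h post-injection) with the exact time jittered uniformly inside
#' the window.
#'
#' The default generating distributions are *plausible placeholders*, not
#' measured population values: effective half-lives of about 50 h (kidneys),
#' 65 h (healthy liver), 70 h (spleen) and 90 h (tumor) with lognormal
#' spread `s = 0.3` on clearance (`s = 0.8` on tumor amplitude, since tumor
#' burden varies over orders of magnitude), a biexponential fraction of 0.3
#' per structure, and a fast uptake phase with half-life about 4 h. Every
#' parameter is configuration; see [cohort_distribution()].
#'
#' @param n_patients Number of virtual patients.
#' @param tumors_per_patient Integer range (length 2) of index tumors drawn
#'   uniformly per patient.
#' @param dists A `cohort_distribution` giving each structure's generating
#'   distribution; defaults to [default_generating_distribution()].
#' @param windows A [time_periods()]-shaped tibble of scan windows.
#' @param noise A [noise_model()] applied to the generated activities, or
#'   `NULL` for noise-free observations.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
synthetic_cohort_config <- function(n_patients = 28,
                                    tumors_per_patient = c(1, 5),
                                    dists = default_generating_distribution(),
                                    windows = time_periods(),
                                    noise = noise_model(a = 0.05, b = -0.4),
                                    seed = 1) {
  if (n_patients < 1) stop("`n_patients` must be >= 1.", call. = FALSE)
  if (length(tumors_per_patient) != 2 ||
      tumors_per_patient[1] < 1 ||
      tumors_per_patient[2] < tumors_per_patient[1]) {
    stop("`tumors_per_patient` must be an increasing range starting >= 1.",
         call. = FALSE)
  }
  if (!all(c("label", "low", "high") %in% names(windows)) ||
      any(windows$low >= windows$high)) {
    stop("`windows` must have label/low/high columns with low < high.",
         call. = FALSE)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         tumors_per_patient = as.integer(tumors_per_patient),
         dists = dists, windows = windows, noise = noise,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Default generating distribution for synthetic cohorts
#'
#' Plausible-placeholder population used by [generate_clinical_cohort()];
#' amplitudes follow the configured concentration ordering
#' liver > spleen > kidney > tumor. `bi_fraction` sets the share of
#' biexponential (uptake-phase) kinetics per structure.
#'
#' @param bi_fraction Fraction of biexponential fit types (0-1, default 0.3).
#' @param s_lambda Lognormal spread of the clearance constant.
#' @return A `cohort_distribution`.
#' @export
default_generating_distribution <- function(bi_fraction = 0.3,
                                            s_lambda = 0.3) {
  mk <- function(structure, C_mu, T_eff_h, s_C = 0.3) {
    lam <- log(2) / T_eff_h
    lam2 <- log(2) / 4      # fast uptake phase, ~4 h half-life
    n_bi <- max(round(10 * bi_fraction), 0)
    labels <- c(rep("mono", 10 - n_bi), rep("bi", n_bi))
    cohort_distribution(
      structure = structure,
      fit_labels = labels,
      mono = list(C = lognormal_spec(s = s_C, mu = C_mu),
                  lambda1 = lognormal_spec(s = s_lambda, mu = lam)),
      bi = if (n_bi > 0) list(
        C = lognormal_spec(s = s_C, mu = C_mu),
        lambda1 = lognormal_spec(s = s_lambda, mu = lam),
        lambda2 = lognormal_spec(s = 0.2, mu = lam2)
      ) else NULL
    )
  }
  c(mk("healthy_liver", C_mu = 250, T_eff_h = 65),
    mk("spleen", C_mu = 100, T_eff_h = 70),
    mk("left_kidney", C_mu = 70, T_eff_h = 50),
    mk("right_kidney", C_mu = 70, T_eff_h = 50),
    mk("tumor", C_mu = 25, T_eff_h = 90, s_C = 0.8))
}

#' Generate a synthetic clinical-like cohort
#'
#' Per patient and structure: draws a ground-truth TAC model from the
#' configured distribution, draws one scan time uniformly inside each of the
#' four windows, evaluates the model activity at those times, and applies
#' measurement noise. Tumors are replicated 1-5 times per patient (labels
#' `tumor_1`, `tumor_2`, ... share the `tumor` generating distribution).
#'
#' @param cfg A [synthetic_cohort_config()].
#' @return A list with `observations` (tibble: `patient_id`, `structure`,
#'   `structure_label`, `time_h`, `activity_MBq`) and `ground_truth`
#'   (tibble: one generating model per curve with its analytic `tia` —
#'   sealed truth for scoring, not an input to any fit).
#' @export
generate_clinical_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  structures <- names(cfg$dists)
  has_tumor <- "tumor" %in% structures
  organ_structs <- setdiff(structures, "tumor")

  obs <- list(); truth <- list(); row <- 0L
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", p)
    n_tum <- if (has_tumor) {
      sample(seq(cfg$tumors_per_patient[1], cfg$tumors_per_patient[2]), 1)
    } else 0L
    labels <- c(organ_structs,
                if (n_tum > 0) paste0("tumor_", seq_len(n_tum)))
    sources <- c(organ_structs, rep("tumor", n_tum))
    for (k in seq_along(labels)) {
      row <- row + 1L
      model <- sample_tac(cfg$dists, sources[k], 1)
      times <- stats::runif(nrow(cfg$windows), cfg$windows$low,
                            cfg$windows$high)
      times <- sort(times)
      a <- eval_activity_params(model$kind, model$C, model$lambda1,
                                model$lambda2, times)
      if (!is.null(cfg$noise)) a <- apply_noise(a, cfg$noise)
      obs[[row]] <- tibble::tibble(
        patient_id = pid, structure = sources[k], structure_label = labels[k],
        time_h = times, activity_MBq = a
      )
      truth[[row]] <- dplyr::mutate(model, patient_id = pid,
                                    structure = sources[k],
                                    structure_label = labels[k], .before = 1)
    }
  }
  list(observations = dplyr::bind_rows(obs),
       ground_truth = dplyr::bind_rows(truth))
}

#' Default phantom objects for noise calibration
#'
#' Seven insert-like objects spanning roughly three orders of magnitude in
#' activity (MBq), mimicking an anthropomorphic abdominal phantom with
#' inserts at several activity concentrations plus background.
#'
#' @return A tibble with columns `object_label`, `activity_MBq`.
#' @export
default_phantom_objects <- function() {
  tibble::tibble(
    object_label = c("liver_insert", "sphere_hot_1", "sphere_hot_2",
                     "ellipsoid_hot", "ellipsoid_mid", "sphere_cold_core",
                     "background"),
    activity_MBq = c(250, 30, 15, 60, 40, 20, 2)
  )
}

#' Default phantom scan lengths
#'
#' Ten acquisition lengths forming a geometric sequence spanning a 16-fold
#' reduction in counts, imitating roughly ten days of physical and
#' biological decay while all measurements are made on one day.
#'
#' @param n Number of scan lengths.
#' @param reference_min Longest (reference) scan length, minutes.
#' @param reduction Total count-reduction factor across the sequence.
#' @return Numeric vector of scan lengths, minutes.
#' @export
default_phantom_scan_lengths <- function(n = 10, reference_min = 25,
                                         reduction = 16) {
  reference_min * reduction^(-(seq_len(n) - 1) / (n - 1))
}

#' Generate a synthetic repeat-phantom measurement table
#'
#' For each object and scan length, computes the effective activity under
#' the 25-minute rule and draws `n_repeats` quantified activities from a
#' normal distribution with SD = `RSD(A_eff) * activity`, where the RSD
#' comes from the supplied ground-truth noise law. The result feeds
#' [fit_noise_model()], closing the loop for noise-calibration tests.
#'
#' @param noise_truth The generating [noise_model()].
#' @param scan_lengths Acquisition lengths, minutes (`>= 2` values).
#' @param n_repeats Repeats per (object, scan length) (default 4).
#' @param objects Tibble with `object_label`, `activity_MBq`.
#' @param reference_min Reference scan length, minutes.
#' @param seed Integer seed.
#' @return A tibble in the phantom CSV schema: `object_label`,
#'   `scan_length_min`, `repeat_index`, `activity_MBq`.
#' @export
generate_phantom_table <- function(noise_truth,
                                   scan_lengths = default_phantom_scan_lengths(),
                                   n_repeats = 4,
                                   objects = default_phantom_objects(),
                                   reference_min = 25,
                                   seed = 1) {
  stopifnot(inherits(noise_truth, "noise_model"))
  if (length(scan_lengths) < 2) {
    stop("at least 2 scan lengths are required.", call. = FALSE)
  }
  if (any(objects$activity_MBq <= 0)) {
    stop("object activities must be > 0.", call. = FALSE)
  }
  set.seed(seed)
  grid <- tidyr::expand_grid(
    object_label = objects$object_label,
    scan_length_min = scan_lengths,
    repeat_index = seq_len(n_repeats)
  ) |>
    dplyr::left_join(objects, by = "object_label")
  a_eff <- effective_activity(grid$activity_MBq, grid$scan_length_min,
                              reference_min)
  sd <- noise_rsd(noise_truth, a_eff) * grid$activity_MBq
  grid$activity_MBq <- pmax(
    stats::rnorm(nrow(grid), mean = grid$activity_MBq, sd = sd), 0)
  dplyr::select(grid, "object_label", "scan_length_min", "repeat_index",
                "activity_MBq")
}
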