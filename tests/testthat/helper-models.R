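# shared fixtures built in code

# noiseless samples from a model at the nominal 4-scan times
samples_from <- function(model, times = c(4, 24, 96, 168)) {
  data.frame(time_h = times, activity_MBq = eval_activity(model, times))
}

# random valid models for property loops
random_models <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    if (stats::runif(1) < 0.5) {
      tac_model("mono", C = stats::runif(1, 1, 500),
                lambda1 = stats::runif(1, 0.002, 0.2))
    } else {
      l1 <- stats::runif(1, 0.002, 0.05)
      tac_model("bi", C = stats::runif(1, 1, 500), lambda1 = l1,
                lambda2 = l1 * stats::runif(1, 1.5, 50))
    }
  })
}

# numeric-integration TIA oracle, independent of analytic_tia()
tia_by_integration <- function(model) {
  stats::integrate(function(t) eval_activity(model, t), 0, Inf,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}

# phantom table with exact (noise-free) power-law RSD per group:
# four symmetric offsets whose sample SD equals rsd * mean exactly
exact_phantom_table <- function(a, b, a_eff = 10^seq(1, 4, length.out = 10)) {
  k <- sqrt(3 / 5)  # sample SD of c(-1.5,-.5,.5,1.5)*k is exactly 1
  do.call(rbind, lapply(seq_along(a_eff), function(i) {
    m <- a_eff[i]
    rsd <- a * m^b
    data.frame(object_label = paste0("obj", i), scan_length_min = 25,
               repeat_index = 1:4,
               activity_MBq = m + c(-1.5, -0.5, 0.5, 1.5) * k * rsd * m)
  }))
}

# one-structure mono-only distribution with configurable spread
mono_only_dist <- function(structure = "kidney", C_mu = 70, T_eff = 50,
                           s = 0.3) {
  cohort_distribution(
    structure = structure, fit_labels = rep("mono", 4),
    mono = list(C = lognormal_spec(s = s, mu = C_mu),
                lambda1 = lognormal_spec(s = s, mu = log(2) / T_eff))
  )
}
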