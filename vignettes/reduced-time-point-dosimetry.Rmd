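---
title: "Accuracy and uncertainty of reduced time point TIA estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accuracy and uncertainty of reduced time point TIA estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtpdosim)
library(dplyr)
```

## The problem

Internal dosimetry for ¹⁷⁷Lu-DOTATATE peptide receptor radionuclide therapy
needs the time-integrated activity (TIA) of each organ at risk and tumor:
the integral of the structure's activity from administration to infinity,
which multiplied by S-values gives absorbed dose. Estimating TIA properly
requires serial quantitative SPECT/CT over about a week — a burden that has
motivated *reduced time point* protocols using one, two or three scans.
Their price is an error in TIA that depends strongly on *when* the scans
happen. `rtpdosim` provides the machinery to quantify that error: exact
time-activity curve (TAC) models, the reduced-time-point estimators, a
virtual-patient simulator with realistic measurement noise, exhaustive
enumeration of admissible imaging schedules, and error summaries that
identify optimal schedules.

## Models and estimators

A structure's TAC is modelled as monoexponential, $A(t) = C e^{-\lambda t}$,
or biexponential with an uptake phase,
$A(t) = C (e^{-\lambda_1 t} - e^{-\lambda_2 t})$, $\lambda_2 > \lambda_1 > 0$.
All decay constants are *effective* (biological + physical); physical decay
is not modelled separately. Ground-truth TIA is analytic: $C/\lambda$ and
$C(1/\lambda_1 - 1/\lambda_2)$ respectively. The strict ordering
$\lambda_2 > \lambda_1$ is enforced at construction — equal constants
collapse the curve to zero — and guarantees a positive, finite TIA.

Reduced time point estimators:

* **Hänscheid**: $\widehat{TIA} = A(t)\, 2t/\ln 2$. On a monoexponential
  truth its relative error is $2x\,2^{-x} - 1$ with $x = t/T_{\mathrm{eff}}$:
  exact at $x = 1$ and $x = 2$, at most $+6.15\%$ (at $x = 1/\ln 2$), and
  grossly low far from the half-life.
* **Madsen**: $\widehat{TIA} = A(t)\, e^{\lambda_{pop} t}/\lambda_{pop}$,
  exact when the patient matches the population decay constant, with
  estimate/truth ratio $(\lambda/\lambda_{pop}) e^{(\lambda_{pop}-\lambda)t}$
  otherwise. Population half-lives are **runtime configuration**
  (`population_kinetics()`): the shipped defaults (kidney 50 h, healthy
  liver 65 h, spleen 70 h, tumor 90 h) are editable placeholders in the
  plausible clinical range, and every report records the values used.
* **2TP**: exact inversion of a monoexponential through two points.
* **3TP** (and the 4-point mono candidate): unweighted least squares in
  activity space.

The 4-point reference fit chooses mono versus bi by AIC,
$n \ln(RSS/n) + 2k$ with $k = 2$ or $3$. Plain AIC is used, not AICc: at
$n = 4$, $k = 3$ the AICc correction divides by zero. RSS is floored at
$10^{-12}$ MBq² to guard $\ln 0$, and ties resolve to the monoexponential.
Four-or-more-parameter exponential sums are deliberately out of scope: with
4 data points they are underconstrained.

### Numerical choices

Least-squares fits are performed in activity space, unweighted — no
weighting scheme is assumed, and additive Gaussian measurement noise makes
this the matching objective. The amplitude enters the residuals linearly,
so it is profiled out in closed form and the monoexponential fit reduces to
a 1-D minimisation over $\lambda$, solved by a fixed deterministic grid
(negative branch down to $-0.08$ h⁻¹ so rising, noise-corrupted data can
settle on an *invalid* fit rather than a distorted one; positive branch
log-spaced over effective half-lives ~0.5–7000 h) plus vectorised
golden-section refinement. This one code path serves both single fits and
the ~800 000 batched 3TP refits of a full simulation, and recovers
noiseless generators to better than $10^{-6}$ relative error. RSS is always
evaluated from residuals, not the profiled shortcut $\sum A^2 - C^2 \sum
f^2$, which cancels catastrophically near exact fits. The biexponential fit
optimises $(\log\lambda_1, \log(\lambda_2-\lambda_1))$ — the transform
enforces the constraints — by Nelder–Mead from a fixed six-point start grid
($\lambda_1 \in \ln 2/\{200,100,50\}$ h⁻¹, $\lambda_2 = m\lambda_1$,
$m \in \{3,10\}$), keeping the best RSS; the grid is seed-free so fits are
deterministic.

Fits with $\lambda \le 0$ (flat or rising data) are returned *flagged
invalid* rather than raising: such fits genuinely occur under measurement
noise and their frequency is part of the result. Error summaries exclude
them from metric means by default but report `n_valid`/`n_total`; a
`penalize` policy instead charges a configurable percent-error cap so that
failure-prone schedules surface in RMSE rankings.

## Sampling schedules

Single-time-point evaluation uses an hourly grid, 1–240 h post-injection
(240 times). Two-point schedules draw from the 4-hour grid 4, 8, …, 240 h
(60 times, 1770 pairs). Three-point schedules respect clinic reality:
assuming injection at the start of day 0, scans may only happen at the
beginning, middle or end of a working day (24k, 24k+4, 24k+8 h; 30 valid
times starting 4 h post-injection) and no two scans may fall on the same
day — every pairwise gap must exceed 12 h, "overnight" gaps between
consecutive days being exactly 16 h and allowed. This reading uniquely
yields the 3294 admissible triples; a brute-force enumeration over all
$\binom{30}{3} = 4060$ triples confirms it in the test suite.

Clinical-style analysis groups each patient's scans into four nominal
windows (3–5, 21–52, 71–126, 144–194 h). Scans falling between windows are
assigned to the nearest boundary with a warning rather than dropped — real
cohorts are analysed in full despite imperfect scheduling.

## Measurement noise

Quantitative SPECT noise is modelled as a power law in *effective activity*
(activity rescaled to a 25-minute reference acquisition):
$RSD(A) = a A^b$. The law is fitted by ordinary least squares on the
log–log transform of per-group (object × scan length) repeat statistics
from a phantom table. Two refinements matter in practice:

* With only 4 repeats per group the sample SD is biased low on the log
  scale by $\tfrac12(\psi(\nu/2) - \ln(\nu/2)) \approx -18\%$ ($\nu = 3$),
  which would propagate into the coefficient $a$. `fit_noise_model()`
  debiases each group's log-RSD with this exact normal-theory correction by
  default (switchable off).
* Zero-variance groups have undefined log-RSD and are excluded with a
  warning; fewer than two usable groups is an error.

Noise injection draws once per sampled point from
$N(A, (RSD(A)\cdot A)^2)$ with the RSD evaluated at the *true* activity.
Negative draws are clamped to zero — not resampled — keeping the draw count
deterministic; clamped zeros invalidate 2TP fits downstream, which is the
intended failure signal. The default truth coefficients ($a = 0.05$,
$b = -0.4$, fractional RSD) give ~0.8% RSD at 100 MBq and ~5% at 1 MBq,
representative of quantitative ¹⁷⁷Lu SPECT; they are configuration like
everything else.

## The virtual-patient study

`derive_cohort_distribution()` turns a table of reference fits into a
per-structure "population prior": observed mono/bi labels (the bootstrap
source) and, per parameter, a lognormal parameterised by $s$ (SD of the log
values) and $\mu$ (exp of the mean of the logs), truncated at the cohort
minimum/maximum. For clearance constants a wider literature half-life range
may replace the cohort bounds — only ever widening them. Sampling is by
rejection (simple, exact, with an attempt cap against misconfiguration);
biexponential $(\lambda_1, \lambda_2)$ pairs are re-drawn *jointly* until
$\lambda_2 > \lambda_1$ so the marginals are not distorted by swapping.

`run_simulation_study()` draws 250 curves per structure (the study
default), evaluates their activity on the hourly grid, adds one noisy
realisation per curve and grid time — shared by every schedule using that
time — and scores every schedule of every family against each curve's
analytic TIA. RNG is hierarchical (seed → structure → stage), so adding or
removing schedule families never perturbs curve generation, and identical
seed + configuration reproduce outputs byte-for-byte.

### What the synthetic generator does and does not emulate

`generate_clinical_cohort()` emulates the *design* of a 28-patient,
four-scan post-therapy cohort: healthy liver, left/right kidney, spleen and
1–5 tumors per patient, scan times jittered uniformly inside the four
windows, measurement noise per the power law. Default kinetics are
plausible placeholders (documented above; tumor amplitude spread $s = 0.8$
reflecting order-of-magnitude burden variation, biexponential fraction 0.3,
uptake half-life ~4 h) chosen once within the ranges reported for
¹⁷⁷Lu-DOTATATE kinetics; they are **not** fitted to any real cohort. The
generator does not model patient covariates, inter-structure correlation
within a patient, volume effects, segmentation error, or kinetics beyond
two exponential terms. Passing tests therefore demonstrate correctness of
the *pipeline* and qualitative transferability of the schedule findings —
not numeric agreement with any particular clinic's patients, whose error
tables depend on unpublished cohort parameters.

### Problem sizes used

The shipped analyses use 250 curves per structure across 5 structures with
all 240 + 1770 + 3294 schedules (~1.4 million estimates, a few minutes on
one CPU); the zero-noise exactness checks use 50 curves, and sampling-error
properties are verified at 50 versus 200 curves. These sizes give
Monte-Carlo standard errors on MPE well below the 5% decision thresholds
the analyses report against.

## Error metrics and reports

Per schedule: RMSE on absolute TIA (MBq·h — deliberately scale-weighted
toward high-uptake cases, the convention of clinical dosimetry tables), MPE
and its sample SD, MAPE, and a normal-approximation 95% CI for MPE (1.96,
not a t quantile; documented and encapsulated in one place). The optimal
schedule is the RMSE argmin, ties broken by the lexicographically earliest
time tuple. `build_reports()` emits the optimal-schedule table, the full
2TP MPE/SD matrices for heatmaps, and the provenance (seed, population
kinetics, noise coefficients); `check_schedule()` answers the companion
question "what error should we expect at *these* times?".

```{r example, eval = FALSE}
sim <- run_simulation_study(default_generating_distribution(),
                            n_curves = 250,
                            noise = noise_model(0.05, -0.4), seed = 1)
build_reports(sim)$optimal
plot_error_heatmap(sim, "sd")
check_schedule(sim, c(24, 96))
```

With the default conditions this reproduces the qualitative findings the
package is built to expose: 2TP schedules pairing a day-1/2 scan with a
day-3/5 scan stay within a few percent MPE; pairing two late, close
together scans inflates dispersion by an order of magnitude (low activity →
large relative noise → unstable or invalid monoexponential inversions); the
single-time-point optima sit near each structure's effective half-life;
Hänscheid is biased positive at its optimum while Madsen is near-unbiased
but more variable away from it; and three-point schedules trade a little
accuracy for visibly lower variability.

## Known limitations

* Mono/bi exponentials only; a two-phase clearance that neither captures
  (e.g. marrow) is out of scope, as are absorbed-dose conversion,
  image-level simulation and segmentation effects.
* The lognormal family for parameter distributions is assumed, not tested,
  here (goodness-of-fit is a cohort-specific question).
* Whether kidneys should be pooled or analysed per side is left to the
  caller: structures are just labels.
* Clinical error tables from any real cohort depend on that cohort's
  distribution parameters; this package reproduces procedures and
  structure, not unpublished numbers.
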