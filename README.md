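# rtpdosim

Accuracy and uncertainty analysis of **reduced time point** time-integrated
activity (TIA) estimation for ¹⁷⁷Lu-DOTATATE internal dosimetry.

Patient-specific dosimetry after peptide receptor radionuclide therapy
needs the TIA of each organ at risk and tumor — the integral
$\tilde A = \int_0^\infty A(t)\,dt$ of the structure's time-activity curve
(TAC), later multiplied by S-values to obtain absorbed dose. Acquiring the
3–4 quantitative SPECT/CT scans that a full TAC fit wants is a burden on
patients and clinics, so single- (STP), two- (2TP) and three-time-point
(3TP) protocols are increasingly used instead. Their error depends strongly
on *when* the scans happen. `rtpdosim` is for medical physicists and
dosimetry researchers who want to quantify that error and pick imaging
schedules: it implements the TAC models and estimators, a virtual-patient
simulator with realistic SPECT measurement noise, exhaustive enumeration of
admissible schedules, and RMSE/MPE/MAPE error summaries with
optimal-schedule search.

## The models and estimators

* TACs: monoexponential $A(t) = C e^{-\lambda t}$ or biexponential
  $A(t) = C(e^{-\lambda_1 t} - e^{-\lambda_2 t})$ with
  $\lambda_2 > \lambda_1 > 0$ (effective decay constants, 1/h); analytic
  TIA $C/\lambda$ or $C(1/\lambda_1 - 1/\lambda_2)$.
* Reference fits: unweighted activity-space least squares; mono vs bi
  chosen by AIC, $n\ln(RSS/n) + 2k$.
* STP estimators: Hänscheid $A(t)\,2t/\ln 2$ and Madsen
  $A(t)\,e^{\lambda_{pop} t}/\lambda_{pop}$ with configurable population
  kinetics.
* 2TP: exact monoexponential inversion; 3TP: monoexponential least squares.
* Measurement noise: power law $RSD(A) = a A^b$ in effective activity,
  fitted from repeat phantom tables by OLS on the log-log data.
* Virtual patients: fit types bootstrapped from a cohort, parameters drawn
  from truncated lognormals ($s$ = SD of log values, $\mu$ = exp of mean
  log), 250 curves per structure, all 240 STP / 1770 2TP / 3294 3TP
  schedules scored against analytic truth.

## Worked example

```r
library(rtpdosim)
library(dplyr)

sim <- run_simulation_study(default_generating_distribution(),
                            n_curves = 250,
                            noise = noise_model(a = 0.05, b = -0.4),
                            seed = 1)
build_reports(sim)$optimal |>
  filter(structure %in% c("left_kidney", "tumor"))
#> # A tibble: 8 × 10
#>   structure   method    schedule      rmse     mpe    sd mpe_sd  mape n_valid n_total
#>   <chr>       <chr>     <chr>        <dbl>   <dbl> <dbl> <chr>  <dbl>   <int>   <int>
#> 1 left_kidney 2tp       12, 164       85.8 -0.144   1.52 -0.1 … 1.14      250     250
#> 2 left_kidney 3tp       8, 104, 168  108.  -0.598   2.37 -0.6 … 1.57      250     250
#> 3 left_kidney hanscheid 74           446.   4.91    6.88 4.9 (… 6.93      250     250
#> 4 left_kidney madsen    79           353.  -1.23    7.03 -1.2 … 5.11      250     250
#> 5 tumor       2tp       16, 232      97.4  0.232    2.01 0.2 (… 1.56      250     250
#> 6 tumor       3tp       24, 216, …  122.   1.15     2.22 1.2 (… 1.88      250     250
#> 7 tumor       hanscheid 153          396.   1.90    7.40 1.9 (… 6.02      250     250
#> 8 tumor       madsen    157          342.  -2.24    7.80 -2.2 … 5.40      250     250
```

Reading the kidney rows: the lowest-RMSE two-point schedule pairs an early
scan (12 h) with a late one (164 h) and estimates TIA essentially without
bias (MPE −0.1%, SD 1.5%, MAPE 1.1% across 250 virtual patients); the
single-time-point optima sit near the kidney's effective half-life
(74–79 h), where Hänscheid carries its characteristic positive bias
(+4.9%) and Madsen is nearly unbiased but more variable. Ask about a
specific protocol with

```r
check_schedule(sim, c(24, 96)) |>
  select(structure, mpe, sd, mape)
#> # A tibble: 5 × 4
#>   structure        mpe    sd  mape
#>   <chr>          <dbl> <dbl> <dbl>
#> 1 healthy_liver  1.37   3.48  2.62
#> 2 left_kidney    2.51   4.42  3.77
#> 3 right_kidney   2.73   4.16  3.66
#> 4 spleen         1.42   3.74  2.82
#> 5 tumor          2.81   4.51  4.02
```

and visualise the full schedule landscape with
`plot_error_heatmap(sim, "sd")`, `plot_stp_error(sim)` or `autoplot(sim)`.
A clinical-style arm (`generate_clinical_cohort()` +
`run_clinical_study()`) runs the same analysis on four-scan cohort tables
grouped into the study's nominal imaging windows.

All population kinetics, noise coefficients and generating distributions
are configuration with documented plausible defaults — see the methods
vignette (`vignettes/reduced-time-point-dosimetry.Rmd`) for the model
assumptions, numerical choices and what the synthetic cohort does and does
not emulate.

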