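# velohrv

Tools for small panel studies of the short-term effect of traffic-related
particulate matter and noise on cardiac autonomic function. The targeted
design is the pre/post-cycling protocol: participants sit for a 40-minute
rest recording before and after each cycling bout (morning and afternoon,
over several days), wearable sensors log beat-to-beat RR intervals at rest
and per-minute PM2.5/PM10 concentrations, A-weighted noise levels and
minute ventilation while riding, and the scientific question is whether the
cumulative doses accumulated during a bout shift the rider's
post-ride-minus-pre-ride change in ECG parameters.

The package covers the full chain:

* **HRV metrics** — cleaning of RR recordings (physiological 30–220 bpm
  range filter plus an iterated running-median ectopy filter), cutting into
  repeated 5-minute windows (up to 8 lags), and the seven standard ECG
  parameters per window: HR, SDNN, pNN50, rMSSD, and the LF (0.04–0.15 Hz),
  HF (0.15–0.40 Hz) band powers and their ratio from a Welch spectrum of
  the resampled tachogram.
* **Exposure doses** — the cumulative inhaled dose
  `I = Σ_minutes VE × 0.001 × C` (µg, from minute ventilation in L/min and
  concentration in µg/m³) and the percentage noise dose
  `D = 100 Σ_i (T_i/T_c) 10^((L_i − L_c)/q)` with a configurable criterion
  level `L_c`, criterion duration `T_c` and exchange parameter `q`,
  including the cutoff-sensitivity curve used to pick `L_c`.
* **Study assembly** — pairing of pre/post rest periods lag by lag (Rest II
  − Rest I in the morning, Rest IV − Rest III in the afternoon) into
  Δ-outcomes, joined with bout doses and confounders, plus descriptive and
  Pearson-correlation reports.
* **Bayesian inference** — for each Δ-outcome, a linear model on a dose,
  confounders (day, period, distance, duration, participant) and
  dose×participant interactions with MA(1) residual autocorrelation across
  successive lags, sampled by a Metropolis-within-Gibbs scheme (conjugate
  β-step, random-walk θ and log σ steps; 4 chains × 4000 iterations, 1000
  warmup), reporting posterior means, 95% credible intervals, split-R̂/ESS
  diagnostics and Savage–Dickey density-ratio Bayes factors (BF10, versus a
  point null at zero).
* **Synthetic studies** — a seed-reproducible generator for the whole
  design (two-tone-plus-noise tachograms, lognormal/normal exposure logs,
  injected dose effects with known ground truth and MA(1) lag noise), so
  every stage is testable end to end without any private data.

## Worked example

```r
library(velohrv)

# percentage noise dose: 65 dB(A) held for 3 h against a 53 dB(A)/24 h
# criterion with exchange parameter q = 10
noise_dose(65, 3, noise_dose_params(lc = 53, tc = 24, q = 10))
#> [1] 198.1116

# how the dose depends on the criterion cutoff (3 h at 71.9 dB(A))
dose_threshold_curve(71.9, cutoffs = c(53, 55, 65, 70, 75), t_hours = 3)
#>   cutoff_dba dose_pct
#> 1         53   970.
#> 2         55   612.
#> 3         65    61.2
#> 4         70    19.4
#> 5         75     6.12
```

A full synthetic study with a known injected effect (0.5 bpm shift in ΔHR
per µg of inhaled PM2.5), analysed end to end:

```r
study <- gen_study(seed = 1)  # 4 participants x 5 days x AM/PM
metrics <- dplyr::bind_rows(lapply(study$rr, compute_hrv_table))
rows <- assemble_analysis_table(pair_rest_periods(metrics),
                                study$bouts, study$bouts)
descriptive_report(rows, c("d_hr", "cum_pm25", "noise_dose"))
#>   variable    mean    sd    min   p25   p50   p75   max   iqr     n
#> 1 d_hr       17.3   9.91  -2.82 10.9  15.9   22.6  62.8  11.7   291
#> 2 cum_pm25   29.8  16.0    7.42 18.6  28.1   31.9 109.   13.3   291
#> 3 noise_dose 20.6   6.52  11.8  15.9  18.7   26.0  43.0  10.1   291

des <- build_design(rows, model_spec("d_hr", doses = "cum_pm25"))
fit <- fit_bayesian_lm(des$y, des$X, des$blocks, sampler_config(seed = 1001))
fit
#> <velohrv_fit> n = 291, p = 12, 12000 draws
#>         term estimate  ci_low ci_high     bf10 rhat   ess
#>  (Intercept)  4.01000 -7.1200  15.100       NA    1 11500
#>     cum_pm25  0.44900  0.2960   0.602 2.58e+09    1 12000
#>          day  0.67200  0.0156   1.340 1.35e-01    1 12000
#>  ...
#>        theta  0.23900  0.1130   0.361       NA    1  2470
#>        sigma  5.96000  5.4800   6.470       NA    1  2450
```

The PM2.5 coefficient recovers the injected 0.5 bpm/µg (posterior mean
0.449, 95% CI 0.296–0.602) with overwhelming evidence for a nonzero effect
(BF10 ≈ 2.6 × 10⁹), while the null interaction terms correctly attract
Bayes factors well below 1; the MA(1) coefficient and residual SD match
the generator's θ = 0.3 and σ = 6.

`run_model_suite(rows, "joint")` fits all seven Δ-outcomes with both doses
at once, and `run_pipeline()` (with `simulate_study()` and a YAML config;
see `?pipeline_config`) orchestrates the file-based version of the same
chain with provenance tracking and byte-reproducible outputs. A thin
command-line wrapper lives at `inst/cli/velohrv.R`.

## Vignette

`vignettes/cycling-exposure-hrv.Rmd` documents the models, the parameter
choices and their defaults, the synthetic-data generator and its
limitations, and the numerical conventions (quantile type, spectral
settings, priors, tie-breaks).
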