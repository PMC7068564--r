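---
title: "Methods: heart rate variability, exposure doses, and Bayesian delta-outcome models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart rate variability, exposure doses, and Bayesian delta-outcome models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(velohrv)
```

# The study design

velohrv analyses pre/post repeated-measures panels in which each
participant, on each study day, completes a morning and an afternoon
cycling bout bracketed by 40-minute seated rest recordings (rest labels
I/II around the morning bout, III/IV around the afternoon bout). The rest
recordings provide beat-to-beat RR intervals; the bouts provide per-minute
exposure logs (PM2.5, PM10, the 1-minute A-weighted equivalent level, and
minute ventilation). The estimand is the effect of the *cumulative dose*
accumulated during a bout on the *change* in each ECG parameter from the
pre-bout rest to the post-bout rest, evaluated window by window within the
rest periods.

# RR cleaning and segmentation

Wearable RR streams contain artefacts: missed or doubled detections and
ectopic beats. Two rules are applied, both configurable via
`cleaning_rules()`:

* a physiological range filter keeping beats with instantaneous heart rate
  in 30–220 bpm (RR in 272.7–2000 ms) — the detection range of typical
  chest-worn sensors and the only hard physical constraint available;
* a running-median ectopy filter (window 11 beats) removing beats that
  deviate from the local median by more than 20 %, iterated until no beat
  is removed, which makes cleaning idempotent by construction.

Removed beats leave *gaps*: surviving beats keep their original time
stamps, so window assignment is unaffected and a heavily corrupted window
simply fails the beat-count check below. The rejection report attached to
the cleaned series keeps every exclusion auditable; with field data the
specific artefact mix is unknowable, so auditable rather than "correct"
exclusion is the design goal.

Segmentation cuts the cleaned recording into half-open 5-minute windows
`[(k-1)·300 s, k·300 s)` anchored at the recording start, at most 8 per
recording. An incomplete trailing window is discarded; the completeness
rule tolerates two median beat intervals at the window end, since a
gap-free 40-minute recording necessarily places its last beat slightly
before the 2400 s mark. Windows with fewer than `min_beats = 100` beats
are flagged invalid: 100 beats in 5 minutes corresponds to 20 bpm, so any
genuinely recorded window passes, while gap-damaged windows fail and are
excluded the way abnormal segments are excluded in practice.

# The seven ECG parameters

Time domain, per window (conventions fixed package-wide):

* HR = 60000 / mean(RR) — the segment's mean heart rate, not the mean of
  instantaneous rates (one convention had to be fixed; this is the common
  reading of "mean HR of the window");
* SDNN = sample standard deviation (n − 1 denominator: a sample statistic
  on a sampled window);
* pNN50 = percentage of the n − 1 successive pairs differing by *strictly*
  more than 50 ms, as the parameter's name says;
* rMSSD = root mean square of successive differences.

Frequency domain: the tachogram is an irregularly sampled series, so it is
cubic-spline interpolated onto a 4 Hz grid, linearly detrended, and its
PSD estimated by Welch's method — 128 s Hann-tapered segments with 50 %
overlap — with rectangle-rule integration of the LF (0.04–0.15 Hz) and HF
(0.15–0.40 Hz) bands, in ms². These are conventional settings for 5-minute
HRV windows; HRV software rarely documents its spectral estimator, so the
estimator here is explicit and every setting is exposed in
`spectral_params()`. When HF is numerically zero the LF/HF ratio is
reported as `NA`, never infinity. The suite checks a Parseval property
(band total within 10 % of the variance of the detrended resampled
signal) and agreement of each tone's band power with a direct periodogram,
which bounds the distortion the estimator chain can introduce.

# Exposure doses

The inhaled dose of a pollutant over one minute is
`VE (L/min) × 0.001 (m³/L) × C (µg/m³)` µg; bout doses sum the minutes.
Minutes with missing VE or concentration are skipped and counted —
the dose then underestimates, which is the conservative, auditable choice
(no interpolation).

The percentage noise dose is the classical criterion-referenced dose

$$D = 100 \sum_i \frac{T_i}{T_c}\, 10^{(L_i - L_c)/q},$$

with each minute contributing \(T_i = 1/60\) h at its 1-minute equivalent
level. `q = 10` corresponds to a 3 dB exchange rate: +3.01 dB doubles the
dose, +10 dB multiplies it by ten, and a constant level \(L_c\) held for
\(T_c\) gives exactly 100 %. The defaults adopt a 70 dB(A)/24 h criterion:
for 2–4 h urban rides with levels around 72 dB(A), lower cutoffs (53 or
55 dB(A)) produce doses in the hundreds of percent while 75 dB(A)
compresses the variability, and `dose_threshold_curve()` reproduces that
trade-off so the choice stays visible rather than baked in. All three
parameters are configurable.

# Delta outcomes and assembly

Δ-outcomes are *post − pre* (Rest II − Rest I, Rest IV − Rest III),
matched lag by lag: lag k of the post-rest is compared with lag k of the
pre-rest. Per-lag pairing (rather than comparing period means) is the
declared choice because the lag sequence itself carries the serial
structure the model uses, and the window count is part of the design.
Unmatched or invalid lags are dropped and counted. Doses and bout
covariates join many-to-one onto the per-lag rows. Descriptive summaries
use type-7 quantiles (linear interpolation between order statistics, the
default convention in scientific software); correlation reports use
Pearson r with two-sided t-test stars at 0.05/0.01/0.001.

# The Bayesian model

For one outcome, with rows sorted by (participant, day, period, lag),

$$y_t = x_t^\top \beta + \varepsilon_t, \qquad
  \varepsilon_t = \eta_t + \theta\, \eta_{t-1}, \qquad
  \eta_t \sim \mathrm{N}(0, \sigma^2),$$

where the MA(1) recursion resets at every (participant, day, period)
block: only successive lags of one rest pair are serially adjacent. The
design contains the dose(s), day, period, distance, duration, participant
dummies (participant 1 reference) and dose×participant interactions.

Priors must be proper for the Savage–Dickey ratio to exist, and weakly
informative to act alike across outcomes whose scales differ by three
orders of magnitude (ΔHR in bpm versus ΔLF in ms²). Data are therefore
standardised internally; on that scale coefficients get N(0, 2.5) priors —
equivalently N(0, 2.5·sd(y)/sd(x_j)) per original-unit coefficient — σ a
half-Student-t(3, 0, sd(y)) prior, and θ a Uniform(−1, 1) prior. Estimates,
intervals and draws are reported back-transformed, so the standardisation
is inert for interpretation (scaling y by c scales the coefficient draws by
exactly c), though, as with any scaled default prior, not for the prior
itself.

Sampling is Metropolis-within-Gibbs: given θ the innovation transform
`z_t = v_t − θ z_{t−1}` (reset per block) reduces the model to an ordinary
Gaussian linear model, so β has an exact conjugate draw; θ and log σ take
random-walk Metropolis steps whose scales adapt toward a 0.44 acceptance
rate during warmup only. The inferential content — posterior means, 95 %
equal-tailed credible intervals, Bayes factors — does not depend on the
sampler brand; defaults mirror the targeted protocol at 4 chains × 4000
iterations with 1000 warmup (12000 retained draws), and every fit reports
split-R̂ and an effective sample size per parameter, flagging (not
erroring on) any R̂ above 1.05. Chains are seeded deterministically from
the configuration seed, so refits are bit-identical.

The Savage–Dickey Bayes factor for a focal coefficient is
`BF10 = p_prior(0) / p_posterior(0)`, the posterior density at zero
estimated by a Gaussian kernel with Silverman's bandwidth on the 12000
draws. BF10 > 1 is evidence *for* a nonzero effect. (Both directions
appear in applied reports; BF10 is this package's declared convention, and
the suite pins the estimator to the conjugate closed form within 5 %.)
When the posterior places essentially no mass at zero the density estimate
underflows; the BF is then capped and flagged rather than returned as
infinity.

# The synthetic-data generator

The generator exists so that every stage can be validated against known
ground truth; it emulates the statistical structure the analysis assumes,
not cardiac physiology.

*Tachograms* are two-tone-plus-noise: a 0.10 Hz LF tone, a 0.25 Hz HF tone
and per-beat white noise around a mean RR, with beat times accumulated from
the intervals themselves. Baseline defaults (mean RR 870 ms, LF amplitude
50 ms, HF amplitude 35 ms, noise SD 30 ms) put the resting metrics in the
range typical of healthy young adults: HR ≈ 69 bpm, SDNN ≈ 50 ms,
LF/HF ≈ 2, pNN50 ≈ 40 %. There is no respiratory coupling, no circadian
drift and no 1/f background, so passing tests demonstrate correctness of
the computational chain on band-structured tachograms — not robustness to
every feature of field recordings.

*Exposure logs* draw per-minute PM2.5 and ventilation from lognormals,
noise levels from a normal, and PM10 as a noisy multiple of PM2.5
(correlation ≈ 0.98). Bout-level means are themselves drawn (PM2.5
lognormal with mean 4.1 and SD 2.1 µg/m³; level N(71.9, 1.2) dB(A);
VE ≈ 40 L/min; distance N(41.7, 5.3) km; duration N(3.0, 0.4) h), which
lands the cumulative doses near 30 µg PM2.5 and 20 % noise dose per bout —
the exposure climate of a low-pollution city in summer.

*Effect injection* happens on the Δ-metric scale, which makes the injected
coefficients exactly the models' estimand. For each bout, the pre-rest
recording is generated from jittered baselines and measured; per-lag
post-rest targets are set to `pre + design × truth + MA(1) noise`
(innovations reset per bout, matching the model's block structure) and
inverted to tachogram parameters: mean RR from the HR target, sine
amplitudes from the band-power targets (subtracting the expected in-band
share of the beat noise), and the beat-noise SD from the SDNN target.
Only HR, SDNN, LF and HF are invertible this way; pNN50, rMSSD and LF/HF
are emergent and excluded from strict recovery claims. Infeasible targets
(negative band power, HR outside 35–200 bpm) are clipped and counted. The
small systematic offset that the inversion approximation leaves in ΔLF/ΔHF
is constant within a study and is absorbed by the model intercept, leaving
dose-coefficient recovery unbiased. Because of dropout-induced adjacency
breaks and the residual measurement noise of the inversion, the *fitted* θ
on study data is mildly attenuated relative to the injected value; the
dedicated MA-coverage check therefore uses directly simulated regression
data.

Default truth injects a 0.5 bpm shift in ΔHR per µg of PM2.5 and a mild
daily drift (0.5 bpm per day), everything else null, with innovation SDs
(ΔHR 6 bpm, ΔSDNN 25 ms, ΔpNN50 12 %, ΔrMSSD 25 ms, ΔLF 300 ms²,
ΔHF 250 ms², ΔLF/HF 1.5) chosen so the marginal spread of each Δ-outcome
is realistic for 5-minute windows once the dose signal is added. A 5 %
independent per-segment dropout emulates abnormal/missing windows, so the
4 × 5 × 2 × 8 = 320-row design ceiling is realised as roughly 280–300
analysed rows.

# Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere; IQR = P75 − P25.
* Spectral floor: HF below 1e−12 ms² ⇒ LF/HF = `NA`.
* Empty level series ⇒ noise dose 0 with a warning; all beats removed ⇒
  a typed condition (`velohrv_empty_after_cleaning`) carrying the
  rejection report; an invalid segment ⇒ `velohrv_insufficient_beats`.
* Rank-deficient designs (possible in very small studies) only affect the
  least-squares *initialisation*, which pivots; the proper priors keep the
  posterior well defined.
* The β-step's Cholesky solve, the innovation transform and the
  random-walk steps are implemented in C++ (RcppArmadillo) and draw from
  R's RNG, so a configuration seed fixes every draw bit for bit.
* Savage–Dickey underflow: posterior density at zero below 1e−10 caps the
  BF and sets a flag.

# Problem sizes used by the test suite

The suite validates the time-domain metrics against a loop-based oracle on
1000 random segments, the spectral chain on two-tone tachograms, the dose
laws exactly, the Bayes-factor estimator against the conjugate closed form
at 12000 draws, full-study effect recovery on the default 4 × 5 × 2 design
at the full default sampler settings, a 20-seed null-calibration study and
a 50-replicate MA(1) coverage study at n = 400 (both at 2 × 1200–2000
sampler settings, which are ample for interval coverage and BF threshold
decisions), and byte-identity of a full pipeline rerun on a 2 × 2 study.

# Known limitations

* The generator's tachograms are stationary two-tone processes; real
  recordings have broadband and nonstationary structure that the cleaning
  and spectral settings have not been tuned against.
* The per-lag pre/post pairing is a declared convention; if a study's
  windows are better compared as period means, assemble accordingly before
  modelling.
* Noise-dose accumulation assigns whole minutes to one level
  (no sub-minute weighting), and skipped minutes underestimate the dose.
* The MA(1) model treats remaining rows within a block as adjacent even
  when an intermediate lag was dropped, which slightly attenuates θ under
  dropout.
* No imputation anywhere: missing rests, lags or minutes reduce the data
  and are reported, never filled in.
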