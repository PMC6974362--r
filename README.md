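# audmark

Markers of multi-talker speech intelligibility in listeners with normal
audiograms: an R pipeline for auditory EEG following responses, adaptive
psychophysics, pupillometry-indexed listening effort, and the cohort-level
model that ties them together.

## The scientific problem

A sizeable fraction of people who seek help for hearing difficulty have
clinically normal audiograms. Their complaint is typically not audibility but
*selective listening* — following one talker among several. Two broad failure
modes are candidates: degraded bottom-up encoding of stimulus temporal fine
structure (sTFS) at early neural stations, and increased top-down cognitive
effort required to extract the target stream. `audmark` implements a battery
that probes both and asks how much of the variance in a multi-talker digit
comprehension threshold each marker explains.

The battery:

- **Speech reception threshold (SRT)** — four-digit report against two
  competing talkers; percent correct vs SNR is fitted by trial-level maximum
  likelihood and the SRT is the 70.71% point (clamped at 0 dB).
- **FM detection threshold** — 2-down-1-up staircase on the excursion depth
  of a 2 Hz FM imposed on a 500 Hz tone (start 75 Hz; factors 1.5 then 1.2;
  geometric mean of the last six reversals per run; median over runs with a
  CV ≤ 0.2 stopping rule).
- **FMFR** — the FM following response. Alternating-polarity epochs are
  summed (cancelling the cochlear microphonic; the half-wave-rectified neural
  component makes the sum periodic at 2F = 1000 Hz) and the 2F phase is
  demodulated with a heterodyne: analytic signal, frequency shift of 1000 Hz
  to 0, exponential filter `exp(-|f|/B)`, inverse DFT, unwrapped phase. A
  depth-d stimulus at rate f_m carries a phase amplitude of `2 d / f_m` rad,
  so depth is recovered as `amp * f_m / 2`; 100-epoch draws repeated 1000
  times stabilize the estimate.
- **IPDFR / EFR** — a 520 Hz carrier, AM at 40.8 Hz, interaural phase
  switching diotic/dichotic 6.8 times per second. The epoch-averaged response
  is read out by sine/cosine projection at exactly 6.8 Hz (IPD following
  response) and 40.8 Hz (envelope following response); their ratio removes
  head-size and electrode gain.
- **ABR wave 1** — zero-phase 300-3000 Hz band-pass, automated
  peak-minus-following-trough in a 1-3 ms window.
- **Pupil effort slope** — blink interpolation (cubic spline), Hampel
  outlier removal, 5-point smoothing; peak fractional dilation per SNR,
  normalized by the light-induced pupil range.
- **Growth metric** — every physiological growth function (FMFR vs depth,
  IPDFR vs total IPD, pupil vs difficulty) is fitted with a 4-parameter
  logistic and reduced to `min-max / half-max`: dynamic range divided by the
  stimulus magnitude at the fit's halfway point.
- **Cohort model** — Pearson marker correlations, then a forward OLS model
  adding predictors in decreasing univariate R² with
  `adjR² = 1 − (1−R²)(N−1)/(N−p−1)` at each step, plus all two-predictor
  models.

No human data ship with the package. A synthetic-data module generates every
input — epoched EEG with separable neural/pre-neural components, continuous
binaural recordings, Bernoulli observers with logistic psychometrics anchored
at the 70.71% staircase convergence point, pupil sessions with blinks and
spikes, and whole cohorts from a calibrated latent-factor model — each with
ground truth attached, so every estimator is validated by parameter recovery.

## Worked example

One synthetic subject, end to end:

```r
library(audmark)

# FMFR growth: 200 epochs/polarity at each depth, bootstrap heterodyne
eeg  <- eeg_sim_spec(neural_gain = 1, cm_gain = 0.5, noise_sd = 0.8, seed = 42)
amps <- sapply(c(2, 5, 8, 10), function(d) {
  resp <- simulate_fm_epochs(eeg, fm_stimulus_spec(depth_hz = d), 200)
  bootstrap_fmfr(resp, n_draw = 100, n_rep = 100, seed = 42)$phase_amp_rad
})
names(amps) <- c(2, 5, 8, 10)
round(amps, 3)
#>     2     5     8    10
#> 1.987 4.986 7.988 9.990

resp0 <- simulate_fm_epochs(eeg, fm_stimulus_spec(depth_hz = 0), 200)
fit <- fit_sigmoid(fmfr_growth(amps, pure_tone_locking(resp0)))
fit
#> <sigmoid_fit: y_min 0, y_max 28.63, x_half 6.121, k 0.3799>
slope_metric(fit)
#> [1] 4.68

# FM detection threshold from staircase runs
obs  <- observer_spec(true_threshold = 8, slope = 4, guess_rate = 0.5)
runs <- collect_runs(staircase_config("fm"), obs, seed = 42)
c(threshold = runs$threshold, n_runs = runs$n_runs)
#> threshold    n_runs
#>      6.43         6

# Speech reception threshold from a full 40-block digits session
sobs <- observer_spec(4, slope = 0.8, guess_rate = digits_guess_rate(),
                      scale = "linear")
res  <- speech_threshold(run_speech_session(speech_protocol(), sobs, seed = 42))
res$srt_db
#> [1] 3.8
round(res$percent_correct)
#> 0 dB 3 dB 6 dB 9 dB
#>    6   58   92  100
```

Reading the numbers: the bootstrap phase amplitudes track the generating
depths (2, 5, 8, 10 Hz) to within ~1%; the fitted growth curve's half-max
sits at 6.1 Hz, giving a slope index of 4.7 (range/half-max, arbitrary
units/Hz); the staircase estimate lands within one fine step-factor of the
observer's true 8 Hz threshold; and the session-level SRT of 3.8 dB sits on
the rising limb of the observer's psychometric (its true 70.71% point is
4 dB), with percent correct falling from 100% at 9 dB SNR to 6% at 0 dB.

On the cohort side, `simulate_cohort()` draws subjects from a latent-factor
model calibrated so the population correlations with the speech outcome are
0.85 (FM threshold), 0.49 (FMFR slope), and 0.53 (pupil slope) while the
physiological markers stay mutually uncorrelated; `forward_model()` then
reproduces the characteristic ordering (pupil first, FMFR second, ABR adding
little).

See `vignettes/speech-in-noise-markers.Rmd` for the full methods account:
model assumptions, parameter defaults with units, numerical conventions, and
what the synthetic generators do and do not emulate.

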