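---
title: "Neural and behavioral markers of multi-talker speech intelligibility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural and behavioral markers of multi-talker speech intelligibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audmark)
```

# The problem

Some listeners with clinically normal audiograms still struggle to follow one
talker among several. `audmark` implements an analysis battery for studying
this: a behavioral speech-in-noise task (multi-talker digit report), two
psychophysical thresholds for temporal fine structure (FM detection and
interaural phase difference detection), three electrophysiological markers
(the FM following response, the IPD following response, and ABR wave 1), a
pupillometric index of listening effort, and a cohort-level regression
linking the markers to the speech outcome. Because human recordings are not
shipped, every stage is driven by a synthetic-data module with known ground
truth, so each estimator can be scored by parameter recovery.

# Stimuli

**FM tone.** A 500 Hz carrier whose instantaneous frequency is
$f(t) = f_c + d\,\sin(2\pi f_m t)$ with $f_m = 2$ Hz and excursion
$d \in \{0, 2, 5, 8, 10\}$ Hz ($d = 0$ is a pure tone). A shallow
quasi-sinusoidal amplitude modulation (rate 1-3 Hz, 6 dB depth) can be added
to suppress excitation-pattern cues in the behavioral task. We implement the
"6 dB modulation depth" as a level trajectory
$a(t) = 10^{\,m \sin(2\pi f_{am} t + \varphi)/40}$ with $m = 6$ dB
peak-to-trough, reading the depth as a level range; the AM start phase is a
spec field (`am_phase_rad`) so synthesis itself stays deterministic and the
behavioral driver owns the randomization.

**IPD train.** A 520 Hz carrier, 100%-depth AM at 40.8 Hz, and a carrier
phase that switches between a diotic and a dichotic state 6.8 times per
second. Because 40.8/6.8 = 6, every switch lands on an AM envelope minimum,
eliminating transition clicks. In the test mode the per-ear shifts
(0, 22.5, 45, 90 degrees) have opposite signs, so the total interaural
difference is twice the per-ear value — all growth curves and outputs use the
*total* IPD axis and say so. The `same_polarity` control shifts both ears
together and carries no interaural difference.

**ABR pip.** 3 kHz, 5 ms, fully shaped by 2.5 ms raised-cosine ramps.
Presentation cadence (11.1/s) and level are metadata for the epoch simulator;
waveform amplitudes are normalized full-scale throughout, since no
calibration chain exists in silico (levels in dB SPL/SL travel as metadata
only).

All synthesis defaults to 25 kHz, the acquisition rate at which every
analysis operates; `write_wav()`/`read_wav()` provide a minimal RIFF
interface for audition.

# Following-response extraction

## Rectified averaging

Cochlear neural responses to low-frequency tones are partially half-wave
rectified, while pre-neural potentials (cochlear microphonic) follow the
stimulus linearly and invert with its polarity. Summing the average responses
to the two stimulus polarities therefore cancels the linear component exactly
and leaves a signal periodic at twice the carrier (2F = 1000 Hz); the
simulator's epochs are
$\text{neural\_gain}\cdot\max(s_p, 0) + \text{cm\_gain}\cdot s_p +
\text{noise}$, which makes the cancellation testable sample-by-sample.
Background noise defaults to a 1/f spectral slope, the realistic regime for
scalp EEG; the exponent is a parameter.

## Heterodyne phase demodulation

The FMFR is quantified from the polarity-summed average by: DFT; discarding
negative frequencies (analytic signal); circularly shifting the spectrum so
1000 Hz maps to 0; applying a zero-phase exponential filter
$H(f) = e^{-|f|/B}$; inverse DFT; unwrapping the phase of the complex
result. After linear detrending (which absorbs any offset between the
heterodyne center and the DFT grid), the phase component at the 2 Hz FM rate
is measured by projection onto sine and cosine at exactly 2 Hz — projection,
not an FFT bin, because it stays exact for any integer number of cycles. The
rectified 2F component carries twice the stimulus excursion, so a depth-$d$
stimulus yields a phase amplitude of $2d/f_m$ radians and the depth estimate
is $\hat d = A_\varphi f_m / 2$.

**Filter bandwidth.** $B$ trades recovery fidelity against noise rejection.
A narrow filter clips the phase-modulation sidebands and biases $\hat d$
down: measured on noiseless inputs, $B = 20$ Hz loses 3.8% at $d = 2$ Hz,
while $B = 100$ Hz keeps the bias below 0.8% at every depth and still
annihilates everything far from the 2F line (after the shift, the 40 Hz
envelope-following region sits ~960 Hz away, where
$e^{-960/100} \approx 10^{-5}$). The default is therefore `filter_bw_hz =
100`, exposed in the interface.

**Bootstrap.** `bootstrap_fmfr()` draws 100 epochs per polarity without
replacement, repeats 1000 times, averages the *phase time-series* across
repetitions, and computes the final amplitude from that mean series. On
noiseless input every subsample is identical and the bootstrap reproduces the
single-pass result exactly, which is tested.

**Normalization.** The growth curve expresses the phase amplitude at each
depth as a fraction of the subject's pure-tone (depth-0) 2F spectral
magnitude. The two quantities have different physical units (radians vs.
volts); the ratio is a per-subject scalar convention that rescales the
curve's dynamic range without moving its half-max point, which is what the
slope metric needs. Subjects with no measurable pure-tone response cannot be
normalized and are excluded with an error.

## IPDFR and EFR

Continuous dichotic recordings are epoched and averaged; amplitudes at the
6.8 Hz transition rate (IPDFR) and the 40.8 Hz AM rate (EFR) are measured by
sine/cosine projection at the exact frequencies — the 294 ms epoch puts
neither target on the DFT grid (1/294.1 ms = 3.4 Hz spacing), so bin lookup
would be wrong by construction. The normalized response is IPDFR/EFR, which
cancels head size and electrode gain; scaling invariance is tested.

**Timing convention.** One epoch is defined as exactly two inter-transition
intervals, $2/6.8\,\mathrm{s} = 294.1$ ms (one shift out of phase and one
back), so 300 epochs span 1.47 min and both targets complete integer cycle
counts per epoch. Epoch boundaries are rounded per epoch, keeping alignment
error below one sample over the full recording. Epoching starts at a
diotic-to-dichotic transition; an `offset_s` parameter realigns imported
data.

**Synthetic binaural response.** Each phase transition — outbound and return
alike — evokes one stereotyped Gaussian deflection (half-width ~20 ms),
scaled by a saturating logistic sensitivity to total IPD (zero at 0 degrees
and in the same-polarity control, pinned to 1 at 180 degrees, midpoint 60
degrees, width 25 degrees). A transition-evoked train is periodic at 6.8 Hz,
matching the observed following response at the transition rate; a
square-wave "state" gate would instead put its fundamental at 3.4 Hz and no
energy at 6.8 Hz at all, which is why the generator is built this way.

**Peak identification.** For locating the dominant spectral component of an
averaged epoch (rather than reading amplitude at a known frequency),
`spectral_peak()` analyzes the periodic extension of the average (20
repetitions, zero-padded FFT, < 0.01 Hz grid). A single 294 ms window has
3.4 Hz resolution, and its edge truncation biases a raw argmax by a few
percent; the periodic extension sharpens each line without adding
information, since the average already estimates one period of the
steady-state response.

# ABR wave 1

The grand average over both polarities cancels any polarity-flipping stimulus
artifact. Averages are band-passed 300 Hz - 3 kHz with a zero-phase
(forward-backward) Butterworth filter, reflection-padded so the IIR transient
does not contaminate the 10 ms epoch. Wave 1 is picked automatically: the
maximum in a fixed 1-3 ms window (required to be a genuine local maximum —
flat or monotone segments raise a no-pick error rather than returning zero),
and the trough is the minimum within 1.5 ms after the peak. Peak-minus-trough
is invariant to DC offset. The fixed windows replace a human picker; they are
the only free choice and are parameters. The simulator builds waves I-V as
biphasic Gaussian deflections at canonical latencies, normalized so the
generating amplitudes *are* the peak-to-trough amplitudes, giving an exact
read-back target.

# Adaptive psychophysics

The 2-down-1-up staircase divides the level by the current factor after two
consecutive correct responses and multiplies after any error; direction
changes are reversals. FM runs start at 75 Hz excursion with factor 1.5 for
the first five reversals and 1.2 for the last seven; IPD starts at 81 degrees
with 4 + 6. The run value is the geometric mean of the last six reversal
levels. The consecutive-correct counter resets after every level change (the
standard transformed up-down convention, which the source procedure leaves
unstated). Runs repeat until the coefficient of variation of the run values
is at most 0.2 (minimum three runs, maximum six); the threshold is the median
run value.

The simulated observer is Bernoulli with a logistic psychometric in *log*
magnitude for FM/IPD (matching the multiplicative steps) and in linear dB SNR
for speech, anchored so that performance at `true_threshold` is exactly
$\sqrt{1/2} = 70.71\%$ — the staircase's convergence point. Monte Carlo over
500 seeded runs puts the mean true percent-correct at the run value within
2 points of 70.71% for moderate psychometric slopes; the residual ~1.5-point
downward bias is the well-known consequence of finite geometric steps and a
finite reversal budget, not an implementation error (it grows with step size
and with psychometric steepness, and vanishes as both shrink).

# Digits task and speech reception threshold

Four practice blocks (5 trials; target-only, 20, 9, 3 dB SNR) are logged but
never fitted. Forty test blocks of eight trials follow: three 20 dB
refreshers, then five trials at the block SNR; block SNRs cycle through
{9, 6, 3, 0} dB, re-randomized every four blocks, so each SNR receives
exactly 50 scored trials. A trial is correct only when all four digits match;
with eight alternatives per digit, chance is $(1/8)^4 \approx 2.4\times
10^{-4}$. The response curve is fitted by maximum likelihood over the 200
Bernoulli test trials (logistic between chance and an upper asymptote with a
lapse term bounded at 0.1) rather than through four percent-correct points —
the trial-level likelihood uses all the data. The speech reception threshold
is the SNR where the fit crosses 70.71% (the same criterion as the adaptive
tasks); crossings below 0 dB are reported as 0, and a curve that never
reaches criterion within 0-20 dB yields an above-range flag, not a number.
Refreshers are excluded from the fit by default (configurable).

# Pupillometry

Preprocessing, in this order: cubic-spline interpolation across blinks and
missing runs (boundary gaps need `edge_mode = "nearest"`), a Hampel filter
(window 7 samples ~ 233 ms at 30 Hz, threshold 3 scaled MADs — conventional
defaults, both parameters exposed), and a centered 5-point moving average
with reflection at the edges so locally linear trends pass unbiased. The
per-block baseline is the mean over the last 0.5 s of each trial's baseline
period, averaged within block (a per-trial option exists). The per-SNR effort
index is the *peak of the across-trial average* fractional change
$(x - b)/b$ over the 2 s digit window — not the average of per-trial peaks,
which would be biased upward by noise. Peaks are normalized by the subject's
bright-to-dark light-induced pupil range, making the metric invariant to
affine recalibration of the pupillometer (gain cancels via the light range,
offset via the fractional change; both invariances are tested). The growth
curve is expressed over task difficulty (dB below the easiest SNR) so that,
like the other growth functions, it increases; a non-positive light range
marks the subject's pupil data unusable.

The simulator emits 30 Hz traces with a gamma-shaped evoked dilation peaking
1.2 s after digit onset whose fractional amplitude grows linearly as SNR
falls, Poisson blinks as missing runs, single-sample spikes, slow baseline
drift, and a bright/dark calibration pair. It does not emulate gaze
artifacts, luminance coupling, or arousal drift beyond the slow baseline
term — recovery tests on it validate the arithmetic of the pipeline, not its
robustness to every failure mode of real eye-tracking data.

# Growth metric

All three physiological growth functions are reduced by the same metric: a
least-squares 4-parameter logistic
$y = y_{\min} + (y_{\max} - y_{\min})/(1 + e^{-k(x - x_{1/2})})$ with
$y_{\min} \ge 0$, $k \ge 0$, and $x_{1/2} \in [\min x,\, 2\max x]$, fitted
from a fixed, deterministic grid of starts (no random restarts); degenerate
data fall back to a flat fit with $k = 0$, so the returned residual never
exceeds the flat fit's. The slope index is
$(y_{\max} - y_{\min}) / x_{1/2}$ — dynamic range over the stimulus magnitude
at the halfway point, in units of 1/x. We use the *fitted* $x_{1/2}$, not an
interpolated data crossing. Note the empirical sign conventions: listeners
with robust monaural FM encoding have *small* FMFR metrics while listeners
sensitive to IPD have *large* IPDFR metrics; that asymmetry is a property of
subjects, not of the metric, and the synthetic cohort reproduces it only at
the correlation level.

# Cohort model

`pearson_matrix()` reports pairwise-complete Pearson correlations with
two-sided t-based p-values and no multiple-testing correction (descriptive,
as flagged in its documentation). `forward_model()` ranks candidate
predictors by univariate $R^2$ against the speech threshold, adds them to an
OLS model in decreasing order, and reports $R^2$ and adjusted
$R^2 = 1 - (1 - R^2)(N-1)/(N-p-1)$ at each step; ties break by the caller's
predictor order, analysis is complete-case with $N$ reported, and collinear
designs fail loudly naming the offending columns. `pairwise_models()` fits
every unordered two-predictor model to expose order effects.

One property worth stating precisely: adding a pure-noise predictor lowers
the adjusted $R^2$ *usually but not in expectation* — the partial F of a
noise regressor is $F(1, n-3)$, whose mean $(n-3)/(n-5)$ exceeds 1, so the
mean change is slightly positive at small $n$ even though the median change
is negative and ~2/3 of draws decrease. The tests assert the median/majority
form.

## Synthetic cohort calibration

Subjects are draws from a three-latent model: temporal coding $T$ (FMFR
slope, loading 0.9), listening effort $E$ (pupil slope, loading 0.9), and an
FM-task-specific factor $F$; the speech threshold loads on all three
(0.544, 0.589, 0.400), and the behavioral FM threshold loads proportionally
to the outcome (0.576, 0.624, 0.423). These values are solved analytically so
the population correlations with the outcome are 0.85 (FM threshold), 0.49
(FMFR), and 0.53 (pupil), while the physiological markers stay mutually
uncorrelated. A two-latent model cannot represent those three correlations:
with FMFR⊥pupil, loading FM only on $T$ forces
$c_T^2 + c_E^2 \ge 0.85^2 + 0.53^2 > 1$. The third factor is the minimal
extension, and it also mirrors the empirical finding that the behavioral FM
task explains outcome variance beyond FMFR + pupil. One implied value is not
free: $r(\text{fm}, \text{fmfr}) = 0.52$ under these defaults. IPDFR, ABR
wave 1, extended high-frequency threshold, and IPD threshold load on nothing.
Markers are emitted on realistic scales by affine transforms, which leave
every correlation untouched.

Parameter-recovery testing uses the analytic sampling theory of Fisher's
$z = \operatorname{atanh}(r)$: over 200 cohorts of $n = 23$, the mean $z$
per calibrated pair must fall within 3 standard errors
($1/\sqrt{(n-3)\cdot 200}$) of $\operatorname{atanh}(\rho) + \rho/(2(n-1))$
(the $O(1/n)$ bias term of Fisher's transform).

# Problem sizes and numerical choices

Test and acceptance runs use: 1 s FMFR averages at 25 kHz (single-epoch
noiseless for recovery checks; 25-30 epochs per polarity with 1/f noise for
bootstrap behavior); 300-epoch (1.47 min) noiseless IPD recordings for
spectral checks and 20-40-epoch recordings elsewhere; 500 staircase runs and
20 full digits sessions for the convergence statistics; 60-200 cohorts for
correlation recovery. Degenerate inputs are errors, not warnings: zero-energy
heterodyne input, empty epoch polarities, non-positive normalization
denominators, boundary blink gaps without an edge policy, flat ABR windows,
and singular regression designs all fail with named messages, because each
corresponds to a subject the original workflow would have excluded explicitly.

# Known limitations

The generators are phenomenological — no cochlear mechanics, no binaural
brainstem model, no talker acoustics (the speech task is modelled at the
response level; the talkers' F0s are protocol metadata). Passing
recovery tests therefore demonstrates that the estimators are unbiased and
stable *under the stated generative assumptions*, not that they are robust to
every artifact of real recordings. The heterodyne assumes the FM rate is slow
relative to the filter bandwidth (quasi-static regime); very fast modulation
rates would need a wider filter and would trade against noise admission.
Axis conventions differ between the two IPD measures and are labelled
everywhere: the adaptive task's levels are per-ear shifts (the staircase
starts at 81 degrees per ear), while the electrophysiological growth axis is
always total IPD (twice the per-ear shift); `growth_curve` objects carry
their axis label to keep the two from being conflated.
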