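#' EEG simulation specification
#'
#' Phenomenological model of a following-response recording: a half-wave
#' rectified phase-locked neural component (auditory-nerve-like), a linear
#' pre-neural component that inverts with stimulus polarity (cochlear
#' microphonic-like), and additive background noise with a configurable
#' spectral slope (1/f by default, the realistic choice for scalp EEG).
#'
#' @param neural_gain amplitude of the half-wave-rectified neural component.
#' @param cm_gain amplitude of the polarity-flipping linear component.
#' @param noise_sd standard deviation of the additive background noise.
#' @param noise_exponent spectral slope of the background: power ~ 1/f^exponent
#'   (0 = white, 1 = pink).
#' @param seed integer seed; every generator is a pure function of
#'   (spec, seed).
#' @return an object of class `eeg_sim_spec`.
#' @export
eeg_sim_spec <- function(neural_gain = 1, cm_gain = 1, noise_sd = 0.5,
                         noise_exponent = 1, seed = 1L) {
  stopifnot(neural_gain >= 0, cm_gain >= 0, noise_sd >= 0,
            noise_exponent >= 0)
  structure(list(neural_gain = neural_gain, cm_gain = cm_gain,
                 noise_sd = noise_sd, noise_exponent = noise_exponent,
                 seed = as.integer(seed)),
            class = "eeg_sim_spec")
}

# Gaussian noise with power spectral density ~ 1/f^exponent, unit variance,
# shaped in the frequency domain.
colored_noise <- function(n, exponent, fs) {
  if (exponent == 0) return(rnorm(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  g <- c(0, f[-1]^(-exponent / 2))          # kill DC
  x <- Re(fft(W * g, inverse = TRUE) / n)
  x / sd(x)
}

# epoch-by-time matrix of independent unit-variance noise rows
noise_matrix <- function(n_epochs, n, exponent, fs) {
  if (exponent == 0) return(matrix(rnorm(n_epochs * n), nrow = n_epochs))
  t(vapply(seq_len(n_epochs), function(i) colored_noise(n, exponent, fs),
           numeric(n)))
}

#' Epoched following-response container
#'
#' Per-polarity epoch-by-time voltage matrices at a common sampling rate,
#' the substrate for rectified averaging.
#'
#' @param epochs_pos,epochs_neg numeric matrices, one row per epoch, for the
#'   positive- and negative-polarity presentations.
#' @param sample_rate_hz sampling rate, Hz.
#' @param stimulus_spec the generating stimulus spec (kept as metadata).
#' @param ground_truth optional list of generating parameters.
#' @return an object of class `epoched_response`.
#' @export
epoched_response <- function(epochs_pos, epochs_neg, sample_rate_hz,
                             stimulus_spec = NULL, ground_truth = NULL) {
  epochs_pos <- as.matrix(epochs_pos); epochs_neg <- as.matrix(epochs_neg)
  if (ncol(epochs_pos) != ncol(epochs_neg))
    stop("epoch length must match across polarities")
  structure(list(epochs_pos = epochs_pos, epochs_neg = epochs_neg,
                 sample_rate_hz = sample_rate_hz,
                 stimulus_spec = stimulus_spec, ground_truth = ground_truth),
            class = "epoched_response")
}

#' @export
print.epoched_response <- function(x, ...) {
  cat(sprintf("<epoched_response: %d (+) / %d (-) epochs x %d samples @ %g Hz>\n",
              nrow(x$epochs_pos), nrow(x$epochs_neg), ncol(x$epochs_pos),
              x$sample_rate_hz))
  invisible(x)
}

#' Simulate alternating-polarity FM following-response epochs
#'
#' Each epoch is `neural_gain * max(s_p, 0) + cm_gain * s_p + noise`, where
#' `s_p` is the stimulus at the epoch's polarity: the neural component
#' half-wave rectifies the stimulus (so the polarity-summed average is
#' periodic at twice the carrier), while the pre-neural component follows it
#' linearly (and so cancels in the sum).
#'
#' @param eeg an [eeg_sim_spec()].
#' @param stim an [fm_stimulus_spec()] (its `polarity` field is overridden per
#'   epoch set).
#' @param n_per_polarity epochs per polarity (the acquisition default is 200).
#' @return an [epoched_response()] with the generating depth in
#'   `ground_truth$depth_hz`.
#' @export
simulate_fm_epochs <- function(eeg, stim, n_per_polarity = 200) {
  stopifnot(inherits(eeg, "eeg_sim_spec"), inherits(stim, "fm_stimulus_spec"),
            n_per_polarity >= 1)
  set.seed(eeg$seed)
  sp <- make_fm_tone(modifyList_spec(stim, polarity = 1))
  sm <- -as.numeric(sp)
  n <- length(sp); fs <- sample_rate(sp)
  gen <- function(s) {
    clean <- eeg$neural_gain * pmax(s, 0) + eeg$cm_gain * s
    m <- matrix(rep(clean, each = n_per_polarity), nrow = n_per_polarity)
    if (eeg$noise_sd > 0)
      m <- m + eeg$noise_sd *
        noise_matrix(n_per_polarity, n, eeg$noise_exponent, fs)
    m
  }
  epoched_response(gen(as.numeric(sp)), gen(sm), fs, stimulus_spec = stim,
                   ground_truth = list(depth_hz = stim$depth_hz,
                                       neural_gain = eeg$neural_gain,
                                       cm_gain = eeg$cm_gain))
}

# rebuild a stimulus spec with some fields replaced (keeps validation)
modifyList_spec <- function(spec, ...) {
  new <- utils::modifyList(unclass(spec), list(...))
  do.call(fm_stimulus_spec, new)
}

#' Continuous-recording container
#' @param samples voltage samples.
#' @param sample_rate_hz sampling rate, Hz.
#' @param stimulus_spec generating [ipd_stimulus_spec()].
#' @param ground_truth list of generating parameters.
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, sample_rate_hz,
                                 stimulus_spec = NULL, ground_truth = NULL) {
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 stimulus_spec = stimulus_spec, ground_truth = ground_truth),
            class = "continuous_recording")
}

# Saturating binaural sensitivity: scaled logistic in total IPD (degrees),
# pinned to 0 at 0 deg and 1 at 180 deg. Zero in the same-polarity control.
ipd_sensitivity <- function(total_ipd_deg, midpoint_deg = 60, width_deg = 25) {
  l <- function(x) plogis((x - midpoint_deg) / width_deg)
  (l(total_ipd_deg) - l(0)) / (l(180) - l(0))
}

#' Simulate a continuous binaural following-response recording
#'
#' Scalp-like signal containing (i) an envelope following response at the AM
#' rate, (ii) a binaural component consisting of one stereotyped deflection per
#' phase transition -- both the outbound (diotic to dichotic) and return
#' transitions evoke a response, so the component is periodic at the
#' transition rate (6.8 Hz) -- scaled by a saturating sensitivity to the total
#' interaural difference, and (iii) background noise. Sensitivity is zero at
#' 0 degrees and in the same-polarity control.
#'
#' @param eeg an [eeg_sim_spec()]; `neural_gain` scales the envelope following
#'   response, `noise_sd` the background.
#' @param stim an [ipd_stimulus_spec()].
#' @param binaural_gain amplitude of the transition-evoked deflection at full
#'   sensitivity.
#' @param deflection_sd_s width (s) of the Gaussian transition deflection.
#' @return a [continuous_recording()]; ground truth stores the sensitivity and
#'   gains.
#' @export
simulate_ipd_recording <- function(eeg, stim, binaural_gain = 1,
                                   deflection_sd_s = 0.02) {
  stopifnot(inherits(eeg, "eeg_sim_spec"), inherits(stim, "ipd_stimulus_spec"))
  if (stim$duration_s < 4 / stim$alt_rate_hz)
    stop("duration must cover several alternation cycles")
  set.seed(eeg$seed)
  fs <- stim$sample_rate_hz
  n <- round(stim$duration_s * fs)
  t <- time_axis(n, fs)
  total_ipd <- if (stim$control_mode == "same_polarity") 0 else
    2 * stim$per_ear_shift_deg
  sens <- ipd_sensitivity(total_ipd)
  efr <- eeg$neural_gain * sin(2 * pi * stim$am_rate_hz * t)
  x <- efr
  if (sens > 0 && binaural_gain > 0) {
    # deflection train: one Gaussian bump per transition, period 1/alt_rate
    t_mod <- (t + 0.5 / stim$alt_rate_hz) %% (1 / stim$alt_rate_hz) -
      0.5 / stim$alt_rate_hz
    x <- x + binaural_gain * sens * exp(-t_mod^2 / (2 * deflection_sd_s^2))
  }
  if (eeg$noise_sd > 0)
    x <- x + eeg$noise_sd * colored_noise(n, eeg$noise_exponent, fs)
  continuous_recording(x, fs, stimulus_spec = stim,
                       ground_truth = list(sensitivity = sens,
                                           efr_gain = eeg$neural_gain,
                                           binaural_gain = binaural_gain))
}

#' Simulate auditory brainstem response epochs
#'
#' Each epoch is a sum of Gaussian-windowed biphasic deflections (waves I-V at
#' canonical millisecond latencies) plus noise. Wave shapes are normalized so
#' the generating `wave_amplitudes` are exactly the peak-to-following-trough
#' amplitudes of the noiseless waves. Stimulus polarity contributes only a
#' small linear artifact (a copy of the pip) that cancels in the two-polarity
#' average.
#'
#' @param wave_amplitudes peak-to-trough amplitudes (uV), one per wave.
#' @param wave_latencies_ms peak latencies (ms), strictly increasing.
#' @param noise_sd additive white-noise SD (uV).
#' @param n_per_polarity epochs per polarity (acquisition default 1000).
#' @param seed integer seed.
#' @param sample_rate_hz sampling rate, Hz.
#' @param epoch_s epoch duration, s.
#' @param artifact_gain amplitude of the polarity-flipping pip artifact.
#' @return an [epoched_response()] with generating amplitudes in ground truth.
#' @export
simulate_abr <- function(wave_amplitudes = c(0.25, 0.15, 0.35, 0.2, 0.4),
                         wave_latencies_ms = c(1.6, 2.7, 3.8, 4.9, 5.9),
                         noise_sd = 1, n_per_polarity = 1000, seed = 1L,
                         sample_rate_hz = 25000, epoch_s = 0.010,
                         artifact_gain = 0.05) {
  stopifnot(length(wave_amplitudes) == length(wave_latencies_ms),
            !is.unsorted(wave_latencies_ms, strictly = TRUE))
  set.seed(as.integer(seed))
  n <- round(epoch_s * sample_rate_hz)
  t_ms <- time_axis(n, sample_rate_hz) * 1000
  wave_shape <- function(lat) {
    # positive peak then trough 0.5 ms later; unit peak-to-trough
    w <- exp(-(t_ms - lat)^2 / (2 * 0.18^2)) -
      0.8 * exp(-(t_ms - lat - 0.5)^2 / (2 * 0.25^2))
    w / (max(w) - min(w[t_ms > lat]))
  }
  clean <- rep(0, n)
  for (k in seq_along(wave_amplitudes))
    clean <- clean + wave_amplitudes[k] * wave_shape(wave_latencies_ms[k])
  pip <- as.numeric(make_abr_pip(sample_rate_hz = sample_rate_hz))
  art <- rep(0, n); art[seq_along(pip)] <- artifact_gain * pip
  gen <- function(pol) {
    base <- clean + pol * art
    m <- matrix(rep(base, each = n_per_polarity), nrow = n_per_polarity)
    if (noise_sd > 0)
      m <- m + matrix(rnorm(n_per_polarity * n, sd = noise_sd),
                      nrow = n_per_polarity)
    m
  }
  epoched_response(gen(1), gen(-1), sample_rate_hz,
                   ground_truth = list(wave_amplitudes = wave_amplitudes,
                                       wave_latencies_ms = wave_latencies_ms))
}
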