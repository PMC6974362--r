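#' Frequency-modulated tone specification
#'
#' Parameters of the FM stimulus used both behaviorally and for the FM
#' following response (FMFR): a 500 Hz carrier whose instantaneous frequency
#' swings `depth_hz` either side of the carrier at `rate_hz`, with a shallow
#' quasi-sinusoidal amplitude modulation (randomized rate between 1 and 3 Hz
#' in the behavioral task) added to suppress cochlear excitation-pattern cues.
#'
#' @param carrier_hz carrier frequency, Hz.
#' @param rate_hz FM rate, Hz.
#' @param depth_hz peak frequency excursion, Hz (0 gives a pure tone).
#' @param duration_s duration, s.
#' @param ramp_s raised-cosine on/off ramp duration, s.
#' @param polarity +1 or -1; -1 negates the waveform (alternating-polarity
#'   presentation).
#' @param am_rate_hz quasi-AM rate, Hz (0 disables the AM).
#' @param am_depth_db peak-to-trough AM depth in dB.
#' @param am_phase_rad AM starting phase in radians. The behavioral task
#'   randomizes this per presentation; synthesis itself stays deterministic,
#'   so randomization is the caller's job.
#' @param sample_rate_hz synthesis rate, Hz. Defaults to 25 kHz, the EEG
#'   acquisition rate at which all downstream analysis operates.
#' @return an object of class `fm_stimulus_spec`.
#' @export
fm_stimulus_spec <- function(carrier_hz = 500, rate_hz = 2, depth_hz = 10,
                             duration_s = 1, ramp_s = 0.005, polarity = 1,
                             am_rate_hz = 0, am_depth_db = 6,
                             am_phase_rad = 0, sample_rate_hz = 25000) {
  if (depth_hz < 0) stop("depth_hz must be >= 0")
  if (depth_hz >= carrier_hz) stop("invalid spec: depth_hz must be < carrier_hz")
  if (sample_rate_hz <= 4 * carrier_hz)
    stop("invalid spec: sample_rate_hz must exceed 4x carrier (2F analysis)")
  if (!polarity %in% c(1, -1)) stop("polarity must be +1 or -1")
  if (duration_s <= 0 || round(duration_s * sample_rate_hz) < 1)
    stop("duration must be a positive multiple of one sample")
  structure(list(carrier_hz = carrier_hz, rate_hz = rate_hz,
                 depth_hz = depth_hz, duration_s = duration_s,
                 ramp_s = ramp_s, polarity = polarity,
                 am_rate_hz = am_rate_hz, am_depth_db = am_depth_db,
                 am_phase_rad = am_phase_rad,
                 sample_rate_hz = sample_rate_hz),
            class = "fm_stimulus_spec")
}

#' Synthesize an FM tone
#'
#' Instantaneous frequency is `carrier + depth * sin(2*pi*rate*t)`; the
#' quasi-AM multiplies the amplitude by `10^(m * sin(2*pi*f_am*t + phase)/40)`
#' so that the level swings over `am_depth_db` dB peak-to-trough; raised-cosine
#' ramps gate onset and offset; `polarity = -1` negates the result.
#'
#' @param spec an [fm_stimulus_spec()].
#' @return a [waveform()].
#' @export
make_fm_tone <- function(spec) {
  stopifnot(inherits(spec, "fm_stimulus_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  t <- time_axis(n, fs)
  # phase = 2*pi*carrier*t + integral of 2*pi*depth*sin(2*pi*rate*t)
  phase <- 2 * pi * spec$carrier_hz * t
  if (spec$depth_hz > 0)
    phase <- phase +
      (spec$depth_hz / spec$rate_hz) * (1 - cos(2 * pi * spec$rate_hz * t))
  s <- sin(phase)
  if (spec$am_rate_hz > 0 && spec$am_depth_db > 0) {
    # +-m/2 dB about the mean level = m dB peak-to-trough
    lev <- (spec$am_depth_db / 2) *
      sin(2 * pi * spec$am_rate_hz * t + spec$am_phase_rad)
    s <- s * 10^(lev / 20)
    s <- s / max(abs(s))                    # renormalize to full scale
  }
  s <- apply_ramps(s, fs, spec$ramp_s)
  waveform(spec$polarity * s, fs)
}

#' Interaural phase difference train specification
#'
#' A 520 Hz carrier, 100%-depth amplitude modulation at 40.8 Hz, and carrier
#' phase that alternates between a diotic and a dichotic state at 6.8
#' transitions per second. The AM rate is an exact multiple of the transition
#' rate so every transition lands on an envelope minimum (no transition
#' artifact). In `opposing` mode the per-ear shifts have opposite signs, so the
#' total interaural difference is twice the per-ear shift; `same_polarity` is
#' the control in which both ears shift together and the interaural difference
#' stays zero.
#'
#' @param carrier_hz carrier, Hz.
#' @param am_rate_hz amplitude-modulation rate, Hz.
#' @param alt_rate_hz phase-transition rate, Hz (transitions per second).
#' @param per_ear_shift_deg per-ear carrier phase shift in degrees, in
#'   \[0, 180\].
#' @param duration_s duration, s.
#' @param level_db_spl presentation level, carried as metadata only.
#' @param control_mode `"opposing"` (test) or `"same_polarity"` (control).
#' @param sample_rate_hz synthesis rate, Hz.
#' @return an object of class `ipd_stimulus_spec`.
#' @export
ipd_stimulus_spec <- function(carrier_hz = 520, am_rate_hz = 40.8,
                              alt_rate_hz = 6.8, per_ear_shift_deg = 90,
                              duration_s = 2 / 6.8 * 300, level_db_spl = 85,
                              control_mode = c("opposing", "same_polarity"),
                              sample_rate_hz = 25000) {
  control_mode <- match.arg(control_mode)
  ratio <- am_rate_hz / alt_rate_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("alignment error: am_rate_hz must be an integer multiple of alt_rate_hz")
  if (per_ear_shift_deg < 0 || per_ear_shift_deg > 180)
    stop("per_ear_shift_deg must lie in [0, 180]")
  structure(list(carrier_hz = carrier_hz, am_rate_hz = am_rate_hz,
                 alt_rate_hz = alt_rate_hz,
                 per_ear_shift_deg = per_ear_shift_deg,
                 duration_s = duration_s, level_db_spl = level_db_spl,
                 control_mode = control_mode,
                 sample_rate_hz = sample_rate_hz),
            class = "ipd_stimulus_spec")
}

#' Synthesize an interaural phase difference train
#'
#' The carrier alternates between diotic and dichotic states; state k spans
#' `[k, k+1) / alt_rate_hz` seconds, with odd states dichotic. Envelope minima
#' of the raised-sine AM coincide with every state transition.
#'
#' @param spec an [ipd_stimulus_spec()].
#' @return a [stereo_waveform()].
#' @export
make_ipd_train <- function(spec) {
  stopifnot(inherits(spec, "ipd_stimulus_spec"))
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  t <- time_axis(n, fs)
  # 100% AM with minima at t = k/alt_rate (since am_rate is a multiple)
  env <- 0.5 * (1 - cos(2 * pi * spec$am_rate_hz * t))
  state <- floor(t * spec$alt_rate_hz) %% 2          # 0 diotic, 1 dichotic
  shift <- spec$per_ear_shift_deg * pi / 180
  sgn_right <- if (spec$control_mode == "opposing") -1 else 1
  left  <- env * sin(2 * pi * spec$carrier_hz * t + state * shift)
  right <- env * sin(2 * pi * spec$carrier_hz * t + state * sgn_right * shift)
  out <- stereo_waveform(left, right, fs)
  attr(out, "spec") <- spec
  out
}

#' Synthesize an ABR tone pip
#'
#' Short gated tone used to evoke auditory brainstem responses; the default is
#' a 3 kHz, 5 ms pip fully shaped by 2.5 ms raised-cosine ramps. Presentation
#' cadence (11.1/s) and level are epoch-simulator metadata, not part of the
#' waveform.
#'
#' @param freq_hz pip frequency, Hz.
#' @param duration_s pip duration, s.
#' @param ramp_s raised-cosine ramp duration, s; must be at most half the
#'   duration.
#' @param polarity +1 or -1.
#' @param sample_rate_hz synthesis rate, Hz.
#' @return a [waveform()].
#' @export
make_abr_pip <- function(freq_hz = 3000, duration_s = 0.005, ramp_s = 0.0025,
                         polarity = 1, sample_rate_hz = 25000) {
  if (ramp_s > duration_s / 2)
    stop("invalid spec: ramp_s must be <= duration_s / 2")
  if (!polarity %in% c(1, -1)) stop("polarity must be +1 or -1")
  n <- round(duration_s * sample_rate_hz)
  t <- time_axis(n, sample_rate_hz)
  s <- sin(2 * pi * freq_hz * t)
  s <- apply_ramps(s, sample_rate_hz, ramp_s)
  waveform(polarity * s, sample_rate_hz)
}
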