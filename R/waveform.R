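#' Sampled waveform containers
#'
#' A `waveform` is a numeric vector of amplitudes with a sampling rate; a
#' `stereo_waveform` holds two equal-length channels. These are the exchange
#' format between stimulus synthesis and all downstream analyses.
#'
#' @param samples numeric vector of finite amplitudes.
#' @param sample_rate_hz sampling rate in Hz (positive scalar).
#' @param left,right numeric vectors of equal length.
#' @return An object of class `waveform` (numeric vector with attributes
#'   `sample_rate_hz`) or `stereo_waveform` (list with `left`, `right`,
#'   `sample_rate_hz`).
#' @export
waveform <- function(samples, sample_rate_hz) {
  stopifnot(is.numeric(samples), length(samples) >= 1,
            is.numeric(sample_rate_hz), length(sample_rate_hz) == 1,
            sample_rate_hz > 0)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  structure(as.numeric(samples), sample_rate_hz = as.numeric(sample_rate_hz),
            class = "waveform")
}

#' @rdname waveform
#' @export
stereo_waveform <- function(left, right, sample_rate_hz) {
  if (length(left) != length(right))
    stop("stereo channels must have equal length")
  if (!all(is.finite(left)) || !all(is.finite(right)))
    stop("waveform samples must be finite")
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 sample_rate_hz = as.numeric(sample_rate_hz)),
            class = "stereo_waveform")
}

#' @export
print.waveform <- function(x, ...) {
  fs <- attr(x, "sample_rate_hz")
  cat(sprintf("<waveform: %d samples @ %g Hz (%.4g s), peak %.4g>\n",
              length(x), fs, length(x) / fs, max(abs(x))))
  invisible(x)
}

#' @export
print.stereo_waveform <- function(x, ...) {
  cat(sprintf("<stereo_waveform: %d samples/channel @ %g Hz (%.4g s)>\n",
              length(x$left), x$sample_rate_hz,
              length(x$left) / x$sample_rate_hz))
  invisible(x)
}

#' Sampling rate of a waveform
#' @param x a `waveform` or `stereo_waveform`.
#' @return sampling rate in Hz.
#' @export
sample_rate <- function(x) {
  if (inherits(x, "stereo_waveform")) return(x$sample_rate_hz)
  attr(x, "sample_rate_hz")
}

# Raised-cosine on/off gate of `ramp_s` seconds applied in place.
apply_ramps <- function(samples, sample_rate_hz, ramp_s) {
  if (ramp_s <= 0) return(samples)
  n <- length(samples)
  nr <- round(ramp_s * sample_rate_hz)
  if (2 * nr > n) stop("ramps longer than the waveform")
  if (nr < 1) return(samples)
  up <- 0.5 * (1 - cos(pi * (0:(nr - 1)) / nr))
  samples[1:nr] <- samples[1:nr] * up
  samples[(n - nr + 1):n] <- samples[(n - nr + 1):n] * rev(up)
  samples
}

time_axis <- function(n, sample_rate_hz) (0:(n - 1)) / sample_rate_hz

#' Spectral amplitude by sinusoidal projection
#'
#' Amplitude of the component at each requested frequency, computed by
#' projecting the (mean-subtracted) signal onto sine and cosine at that exact
#' frequency. Unlike an FFT-bin lookup this is exact for frequencies that do
#' not fall on the DFT grid, provided the window spans an integer number of
#' cycles; off-integer windows incur ordinary leakage.
#'
#' @param x a `waveform` (or plain numeric vector with `sample_rate_hz` given).
#' @param freqs_hz frequencies to evaluate, in Hz.
#' @param sample_rate_hz required when `x` is not a `waveform`.
#' @param demean subtract the mean before projecting (default TRUE).
#' @return numeric vector of amplitudes, one per frequency, in the units of `x`
#'   (a unit-amplitude sinusoid at an evaluated frequency returns 1).
#' @export
projection_amplitude <- function(x, freqs_hz, sample_rate_hz = NULL,
                                 demean = TRUE) {
  fs <- if (is.null(sample_rate_hz)) sample_rate(x) else sample_rate_hz
  if (is.null(fs)) stop("sample_rate_hz required")
  x <- as.numeric(x)
  if (demean) x <- x - mean(x)
  t <- time_axis(length(x), fs)
  vapply(freqs_hz, function(f) {
    a <- 2 * mean(x * cos(2 * pi * f * t))
    b <- 2 * mean(x * sin(2 * pi * f * t))
    sqrt(a^2 + b^2)
  }, numeric(1))
}

#' Write a waveform to a RIFF WAV file
#'
#' Minimal mono/stereo writer for audition and debugging of synthesized
#' stimuli. 16-bit PCM or 32-bit IEEE float. Amplitudes are written as-is for
#' float, or scaled by 32767 (and clipped at full scale) for PCM.
#'
#' @param x a `waveform` or `stereo_waveform`.
#' @param path output file path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  if (inherits(x, "stereo_waveform")) {
    ch <- rbind(x$left, x$right); fs <- x$sample_rate_hz
  } else {
    ch <- rbind(as.numeric(x)); fs <- sample_rate(x)
  }
  n_ch <- nrow(ch); n <- ncol(ch)
  inter <- as.vector(ch)                      # interleaved frames
  bytes_per <- bits / 8
  block <- n_ch * bytes_per
  data_bytes <- n * block
  fmt_code <- if (bits == 16) 1L else 3L      # PCM / IEEE float
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(as.integer(n_ch), con, size = 2, endian = "little")
  writeBin(as.integer(round(fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(fs) * block), con, size = 4, endian = "little")
  writeBin(as.integer(block), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bits == 16) {
    pcm <- as.integer(pmax(-32767, pmin(32767, round(inter * 32767))))
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' Companion reader used for round-trip checks; supports the same subset
#' (16-bit PCM / 32-bit float, canonical 44-byte header).
#'
#' @param path file path.
#' @return a `waveform` or `stereo_waveform`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readChar(con, 4); if (!identical(hdr, "RIFF")) stop("not RIFF")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  readChar(con, 8)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  fmt <- readBin(con, integer(), size = 2, endian = "little")
  n_ch <- readBin(con, integer(), size = 2, endian = "little")
  fs <- readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 4, endian = "little")
  readBin(con, integer(), size = 2, endian = "little")
  bits <- readBin(con, integer(), size = 2, endian = "little")
  readChar(con, 4)
  nb <- readBin(con, integer(), size = 4, endian = "little")
  if (bits == 16) {
    raw <- readBin(con, integer(), n = nb / 2, size = 2, endian = "little",
                   signed = TRUE) / 32767
  } else {
    raw <- readBin(con, numeric(), n = nb / 4, size = 4, endian = "little")
  }
  if (n_ch == 2) {
    idx <- seq(1, length(raw), by = 2)
    stereo_waveform(raw[idx], raw[idx + 1], fs)
  } else waveform(raw, fs)
}
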