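#' Specify a missing-fundamental harmonic complex
#'
#' A harmonic complex tone whose fundamental (harmonic order 1) carries no
#' spectral energy: the sounding partials are the consecutive harmonics
#' \code{n_min, ..., n_min + n_harmonics - 1} of \code{f0_hz}. Such sounds are
#' ambiguous: listeners perceive their pitch either at the (missing)
#' periodicity frequency F0 or at a sounding harmonic, typically the lowest
#' one, whose frequency \code{n_min * f0_hz} is taken as the spectral pitch
#' F_SP.
#'
#' @param f0_hz fundamental (periodicity) frequency in Hz; not physically
#'   present in the spectrum.
#' @param n_min lowest harmonic order with spectral energy (integer >= 2, so
#'   the fundamental is missing).
#' @param n_harmonics number N of consecutive sounding harmonics (integer >= 2
#'   for battery stimuli; single-component specs are allowed for testing).
#' @param duration_s tone duration in seconds.
#' @param fade_s linear fade-in/out duration in seconds.
#' @param id unique label; autogenerated from the parameters if missing.
#' @return an object of class \code{harmonic_complex}.
#' @export
harmonic_complex <- function(f0_hz, n_min, n_harmonics, duration_s = 0.6,
                             fade_s = 0.010, id = NULL) {
  stopifnot(is.numeric(f0_hz), length(f0_hz) == 1L, is.finite(f0_hz))
  if (f0_hz <= 0) stop("f0_hz must be positive")
  n_min <- as.integer(n_min)
  n_harmonics <- as.integer(n_harmonics)
  if (n_min < 2L) stop("n_min must be >= 2: the fundamental must be missing")
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (duration_s <= 0 || fade_s < 0 || 2 * fade_s > duration_s)
    stop("invalid duration/fade combination")
  if (is.null(id))
    id <- sprintf("hc_f0%.4f_n%d_N%d", f0_hz, n_min, n_harmonics)
  structure(
    list(f0_hz = f0_hz, n_min = n_min, n_harmonics = n_harmonics,
         duration_s = duration_s, fade_s = fade_s, id = id),
    class = "harmonic_complex")
}

#' @export
print.harmonic_complex <- function(x, ...) {
  cat(sprintf(
    "<harmonic_complex %s> F0 = %.2f Hz (missing), harmonics %d..%d (%.0f..%.0f Hz), %.3g s\n",
    x$id, x$f0_hz, x$n_min, x$n_min + x$n_harmonics - 1L,
    x$f0_hz * x$n_min, x$f0_hz * (x$n_min + x$n_harmonics - 1L), x$duration_s))
  invisible(x)
}

#' Spectral pitch frequency of a harmonic complex
#'
#' The spectral pitch F_SP is taken as the frequency of the lowest sounding
#' harmonic, \code{n_min * f0_hz}. Alternatively the amplitude-weighted
#' spectral centroid of the sounding partials can be used.
#'
#' @param spec a \code{harmonic_complex}.
#' @param method \code{"n_min"} (default) or \code{"centroid"}.
#' @return frequency in Hz.
#' @export
spectral_pitch <- function(spec, method = c("n_min", "centroid")) {
  method <- match.arg(method)
  if (method == "n_min") return(spec$f0_hz * spec$n_min)
  lv <- harmonic_levels(spec)
  a <- 10^(lv$level_db / 20)
  sum(a * lv$freq_hz) / sum(a)
}

# Log-linear spectral attenuation (dB, cumulative): 0 dB up to 1 kHz, falling
# to -3 dB at 3 kHz and by a further -17 dB to -20 dB at 15.9 kHz, held
# constant above.
spectral_attenuation_db <- function(freq_hz) {
  a <- numeric(length(freq_hz))
  seg1 <- freq_hz > 1000 & freq_hz <= 3000
  a[seg1] <- -3 * (log(freq_hz[seg1] / 1000) / log(3))
  seg2 <- freq_hz > 3000
  f2 <- pmin(freq_hz[seg2], 15900)
  a[seg2] <- -3 - 17 * (log(f2 / 3000) / log(15900 / 3000))
  a
}

#' Harmonic frequencies and levels of a missing-fundamental complex
#'
#' Levels follow a spectral roll-off of -5 dB per harmonic order starting at
#' 0 dB for the lowest sounding harmonic (the level reference), plus a
#' log-linear attenuation of -3 dB from 1 to 3 kHz and a further -17 dB from
#' 3 to 15.9 kHz (held beyond).
#'
#' @param spec a \code{harmonic_complex}.
#' @param sample_rate_hz sampling rate used for the Nyquist check.
#' @return data.frame with columns \code{order}, \code{freq_hz},
#'   \code{level_db}.
#' @export
harmonic_levels <- function(spec, sample_rate_hz = 44100) {
  orders <- spec$n_min + seq_len(spec$n_harmonics) - 1L
  freq <- orders * spec$f0_hz
  bad <- freq >= sample_rate_hz / 2
  if (any(bad))
    stop(sprintf("harmonic order %d (%.1f Hz) at or above Nyquist (%.1f Hz)",
                 orders[which(bad)[1]], freq[which(bad)[1]], sample_rate_hz / 2))
  level <- -5 * (orders - spec$n_min) + spectral_attenuation_db(freq)
  data.frame(order = orders, freq_hz = freq, level_db = level)
}

#' Synthesize a missing-fundamental complex tone
#'
#' Sum of sine-phase sinusoids at the sounding harmonics with amplitudes
#' \code{10^(level_db/20)}, linear fade-in/out ramps, and peak normalization
#' to the given headroom. Deterministic for a given spec.
#'
#' @param spec a \code{harmonic_complex}.
#' @param sample_rate_hz sampling rate (Hz); must exceed twice the highest
#'   harmonic frequency.
#' @param headroom_dbfs peak level in dB full scale (<= 0).
#' @return numeric vector of samples with attributes \code{sample_rate_hz}.
#' @export
synthesize_complex <- function(spec, sample_rate_hz = 44100,
                               headroom_dbfs = -3) {
  lv <- harmonic_levels(spec, sample_rate_hz)
  n <- round(spec$duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1) / sample_rate_hz
  amps <- 10^(lv$level_db / 20)
  x <- numeric(n)
  for (k in seq_along(amps))
    x <- x + amps[k] * sin(2 * pi * lv$freq_hz[k] * t)
  nf <- max(1L, round(spec$fade_s * sample_rate_hz))
  ramp <- seq(0, 1, length.out = nf)
  x[seq_len(nf)] <- x[seq_len(nf)] * ramp
  x[n - nf + seq_len(nf)] <- x[n - nf + seq_len(nf)] * rev(ramp)
  peak <- max(abs(x))
  if (peak > 0) x <- x * (10^(headroom_dbfs / 20) / peak)
  attr(x, "sample_rate_hz") <- sample_rate_hz
  x
}

#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal mono RIFF/WAVE writer for stimulus export.
#'
#' @param x numeric samples in [-1, 1].
#' @param path output file path.
#' @param sample_rate_hz sampling rate; defaults to the waveform attribute.
#' @return \code{path}, invisibly.
#' @export
write_wav <- function(x, path, sample_rate_hz = attr(x, "sample_rate_hz")) {
  if (is.null(sample_rate_hz)) sample_rate_hz <- 44100
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
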