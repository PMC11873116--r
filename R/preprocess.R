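# Preprocessing chain applied to every recording before feature
# extraction: amplitude normalization -> (decimation for wide-band
# recordings) -> silence trimming -> longest voiced segment -> fixed
# 1.5 s center clip for spectrograms.

#' Rescale a waveform to peak amplitude 1
#'
#' @param w a [Waveform-class] with at least one non-zero sample.
#' @return Waveform with `max(abs(samples)) == 1`; shape preserved up to a
#'   positive scale (idempotent).
#' @export
normalizeAmplitude <- function(w) {
  stopifnot(is(w, "Waveform"))
  peak <- max(abs(w@samples))
  if (peak == 0) stop("degenerate input: all-zero waveform cannot be normalized")
  waveform(w@samples / peak, w@fs, provenance = paste0(w@provenance, "|norm"))
}

#' Decimate a waveform by an integer factor
#'
#' An anti-aliasing low-pass FIR (windowed sinc, Blackman window, cutoff at
#' 80% of the new Nyquist, > 60 dB alias suppression) is applied before
#' every `factor`-th sample is retained. This mirrors the down-sampling of
#' 44.1 kHz smartphone recordings by a factor of 5 to 8820 Hz so that the
#' same analysis models apply to telephone- and smartphone-band material.
#'
#' @param w a [Waveform-class].
#' @param factor integer decimation factor (>= 1; 1 is the identity).
#' @return Waveform at `sampleRate(w) / factor`.
#' @export
decimateWaveform <- function(w, factor) {
  stopifnot(is(w, "Waveform"))
  if (factor != round(factor) || factor < 1) stop("'factor' must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(w)
  nyq_new <- w@fs / (2 * factor)
  tw <- 0.2 * nyq_new                       # transition band ends at 0.9 * new Nyquist
  n_taps <- as.integer(ceiling(5.5 * w@fs / tw))
  h <- firLowpass(0.8 * nyq_new, w@fs, n_taps)
  y <- filterFIR(w@samples, h)
  y <- y[seq(1L, length(y), by = factor)]
  y <- pmin(pmax(y, -1), 1)
  waveform(y, w@fs / factor, provenance = paste0(w@provenance, "|dec", factor))
}

#' Trim leading and trailing silence by short-time energy
#'
#' Frame energies are computed in a sliding window; the retained interval
#' spans the first through the last frame whose energy exceeds
#' `rel_threshold` times the maximum frame energy.
#'
#' @param w a [Waveform-class] of duration at least `win_s`.
#' @param win_s analysis window, seconds (default 25 ms).
#' @param hop_s hop, seconds (default 10 ms).
#' @param rel_threshold energy threshold relative to the maximum frame
#'   energy (default 0.01, i.e. -20 dB).
#' @return A list with elements `waveform` (trimmed [Waveform-class]),
#'   `start_s`/`end_s` (retained boundaries in the input time axis) and
#'   `frame_energy` (the short-time energy track, for inspection).
#' @export
trimSilence <- function(w, win_s = 0.025, hop_s = 0.010, rel_threshold = 0.01) {
  stopifnot(is(w, "Waveform"))
  win <- as.integer(round(win_s * w@fs))
  hop <- max(1L, as.integer(round(hop_s * w@fs)))
  if (length(w@samples) < win) stop("input shorter than the analysis window")
  starts <- frameStarts(length(w@samples), win, hop)
  energy <- vapply(starts, function(s) sum(w@samples[s:(s + win - 1L)]^2), numeric(1))
  keep <- which(energy > rel_threshold * max(energy))
  if (max(energy) == 0 || length(keep) == 0L)
    stop("degenerate input: no frame exceeds the energy threshold (pure silence)")
  i0 <- starts[keep[1L]]
  i1 <- min(starts[keep[length(keep)]] + win - 1L, length(w@samples))
  out <- waveform(w@samples[i0:i1], w@fs, provenance = paste0(w@provenance, "|trim"))
  list(waveform = out, start_s = (i0 - 1L) / w@fs, end_s = i1 / w@fs,
       frame_energy = energy)
}

# Frame-wise voicing decision: normalized autocorrelation peak in the
# 60-500 Hz lag range above `strength_min` AND frame energy above 1% of
# the maximum frame energy.
voicedFrames <- function(w, win_s = 0.040, hop_s = 0.010, strength_min = 0.45,
                         fmin = 60, fmax = 500) {
  win <- as.integer(round(win_s * w@fs))
  hop <- max(1L, as.integer(round(hop_s * w@fs)))
  starts <- frameStarts(length(w@samples), win, hop)
  lag_min <- max(2L, as.integer(floor(w@fs / fmax)))
  lag_max <- as.integer(ceiling(w@fs / fmin))
  energy <- numeric(length(starts)); strength <- numeric(length(starts))
  for (i in seq_along(starts)) {
    fr <- w@samples[starts[i]:(starts[i] + win - 1L)]
    fr <- fr - mean(fr)
    energy[i] <- sum(fr^2)
    if (energy[i] <= 0) next
    r <- normalizedAutocorr(fr, min(lag_max, win - 1L))
    if (lag_min <= length(r)) strength[i] <- max(r[lag_min:length(r)])
  }
  voiced <- strength > strength_min & energy > 0.01 * max(energy)
  list(starts = starts, win = win, hop = hop, voiced = voiced,
       strength = strength, energy = energy)
}

#' Extract the longest continuous voiced segment
#'
#' Frames are classified voiced when their normalized-autocorrelation peak
#' (60--500 Hz lag range) exceeds the voicing threshold (0.35 here — more
#' permissive than the 0.45 used for pitch estimation, since severely
#' aperiodic pathological voices are still phonation) and their energy is
#' above the silence floor. Gaps of up to 3 frames (30 ms) inside voiced
#' runs are bridged before the longest contiguous run is returned, so
#' transient distortions do not fragment a sustained vowel. Vowels
#' interrupted by breaths or repetitions are thereby reduced to their
#' single longest phonation.
#'
#' @param w a (trimmed) [Waveform-class].
#' @return The [Waveform-class] covering the longest voiced run.
#' @export
longestVoicedSegment <- function(w) {
  stopifnot(is(w, "Waveform"))
  vf <- voicedFrames(w, strength_min = 0.35)
  if (!any(vf$voiced)) stop("degenerate input: no voiced frame found")
  # bridge short unvoiced gaps (closing)
  g <- rle(vf$voiced)
  interior <- seq_along(g$values)[-c(1L, length(g$values))]
  fill <- which(!g$values & g$lengths <= 3L)
  g$values[intersect(fill, interior)] <- TRUE
  vf$voiced <- inverse.rle(g)
  r <- rle(vf$voiced)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- vf$starts[begins[best]]
  i1 <- min(vf$starts[ends[best]] + vf$win - 1L, length(w@samples))
  waveform(w@samples[i0:i1], w@fs, provenance = paste0(w@provenance, "|voiced"))
}

#' Clip a fixed-duration segment from the middle of a recording
#'
#' Spectrogram images are generated from exactly 1.5 s taken from the
#' middle of each recording; recordings shorter than the clip are excluded
#' from analysis (a `too-short` error is raised).
#'
#' @param w a [Waveform-class].
#' @param clip_s clip duration in seconds (default 1.5).
#' @return Waveform of exactly `round(clip_s * sampleRate(w))` samples
#'   centered on the input midpoint.
#' @export
centerClip <- function(w, clip_s = 1.5) {
  stopifnot(is(w, "Waveform"))
  n_out <- as.integer(round(clip_s * w@fs))
  n <- length(w@samples)
  if (n < n_out)
    stop("too-short: recording is ", sprintf("%.3f", n / w@fs),
         " s, shorter than the ", clip_s, " s clip")
  i0 <- floor((n - n_out) / 2) + 1L
  waveform(w@samples[i0:(i0 + n_out - 1L)], w@fs,
           provenance = paste0(w@provenance, "|clip", clip_s))
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed order: normalize, decimate (when the input rate exceeds
#' `analysis_fs`), trim silence, select the longest voiced segment. The
#' result is the segment used for phonation and spectral features; apply
#' [centerClip()] to it for spectrograms. Re-running the chain on its own
#' output reproduces the same segment.
#'
#' @param w a [Waveform-class].
#' @param analysis_fs target analysis rate in Hz; inputs at an integer
#'   multiple of it are decimated (default 8820 = 44100 / 5; telephone
#'   material at 8000 Hz passes through unchanged).
#' @param min_s minimum duration after trimming; shorter recordings raise
#'   a `too-short` error (default 1.5 s).
#' @return Preprocessed [Waveform-class].
#' @export
preprocessWaveform <- function(w, analysis_fs = 8820, min_s = 1.5) {
  w <- normalizeAmplitude(w)
  if (w@fs > analysis_fs) {
    factor <- w@fs / analysis_fs
    if (abs(factor - round(factor)) > 1e-9)
      stop("input rate ", w@fs, " is not an integer multiple of analysis_fs ", analysis_fs)
    w <- decimateWaveform(w, round(factor))
  }
  w <- trimSilence(w)$waveform
  w <- longestVoicedSegment(w)
  if (duration(w) < min_s)
    stop("too-short: recording is ", sprintf("%.3f", duration(w)),
         " s after trimming (minimum ", min_s, " s)")
  w
}
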