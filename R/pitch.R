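# Frame-based normalized-autocorrelation pitch tracking and glottal cycle
# extraction — the substrate for jitter, shimmer and HNR.

#' Track the fundamental frequency of a voiced waveform
#'
#' Frame-based pitch estimation: within each analysis frame (three periods
#' of `fmin`, 10 ms hop) the normalized autocorrelation is evaluated over
#' the lag range corresponding to `[fmin, fmax]`; the highest peak,
#' refined by parabolic interpolation, gives the frame F0. Frames whose
#' peak falls below the voicing threshold (0.45) or whose energy is below
#' the silence floor are reported as unvoiced (`f0 = 0`).
#'
#' @param w a [Waveform-class] of duration at least `3 / fmin`.
#' @param fmin,fmax pitch search range, Hz (default 60--500, covering
#'   adult speakers with margin).
#' @return A [PitchTrack-class].
#' @export
trackPitch <- function(w, fmin = 60, fmax = 500) {
  stopifnot(is(w, "Waveform"))
  if (duration(w) < 3 / fmin)
    stop("input too short for pitch tracking (< ", sprintf("%.3f", 3 / fmin), " s)")
  win <- as.integer(round(3 / fmin * w@fs))
  hop <- max(1L, as.integer(round(0.010 * w@fs)))
  starts <- frameStarts(length(w@samples), win, hop)
  lag_min <- max(2L, as.integer(floor(w@fs / fmax)))
  lag_max <- min(as.integer(ceiling(w@fs / fmin)), win - 1L)
  n_fr <- length(starts)
  f0 <- numeric(n_fr); strength <- numeric(n_fr); energy <- numeric(n_fr)
  for (i in seq_len(n_fr)) {
    fr <- w@samples[starts[i]:(starts[i] + win - 1L)]
    fr <- fr - mean(fr)
    energy[i] <- sum(fr^2)
    if (energy[i] <= 0) next
    r <- normalizedAutocorr(fr, lag_max)
    seg <- r[lag_min:lag_max]
    rmax <- max(seg)
    # octave robustness: among local maxima within a small tolerance of
    # the global peak, take the shortest lag (subharmonic lags of a
    # periodic signal score equally high)
    m <- length(seg)
    is_peak <- if (m > 2L)
      c(FALSE, seg[2:(m - 1L)] >= seg[1:(m - 2L)] &
               seg[2:(m - 1L)] >= seg[3:m], FALSE)
    else rep(TRUE, m)
    cand <- which(is_peak & seg >= rmax - 0.02)
    j <- if (length(cand)) cand[1L] else which.max(seg)
    peak_lag <- lag_min + j - 1L
    pp <- parabolicPeak(r, peak_lag)
    strength[i] <- pp[2L]
    f0[i] <- w@fs / (peak_lag + pp[1L])
  }
  voiced <- strength > 0.45 & energy > 0.01 * max(energy)
  f0[!voiced] <- 0
  f0[f0 > fmax | (f0 > 0 & f0 < fmin)] <- 0
  # residual octave-error correction: rescale frames whose F0 is near an
  # integer multiple/submultiple of the track median
  v <- f0 > 0
  if (sum(v) >= 3L) {
    med <- stats::median(f0[v])
    for (i in which(v)) {
      if (f0[i] < 0.66 * med) {
        k <- round(med / f0[i])
        if (k >= 2 && abs(f0[i] * k - med) / med < 0.25) f0[i] <- f0[i] * k
      } else if (f0[i] > 1.5 * med) {
        k <- round(f0[i] / med)
        if (k >= 2 && abs(f0[i] / k - med) / med < 0.25) f0[i] <- f0[i] / k
      }
    }
  }
  new("PitchTrack", times = (starts - 1L + win / 2) / w@fs, f0 = f0,
      strength = strength)
}

#' Extract glottal cycles from a waveform guided by a pitch track
#'
#' Waveform-matching cycle marking: starting from the strongest peak in
#' the first period, each successive period is the lag within
#' `[0.8 T, 1.25 T]` (local period `T` from the pitch track) that
#' maximizes the normalized cross-correlation between the current cycle's
#' waveform and its shifted continuation, refined to sub-sample precision
#' by parabolic interpolation. This measures period increments from the
#' whole cycle shape rather than from a single peak, which is what makes
#' small (sub-sample) jitter recoverable. Per-cycle amplitudes are the
#' parabolically interpolated waveform maxima within each cycle.
#'
#' @param w a [Waveform-class].
#' @param pt a [PitchTrack-class] of `w` with at least 5 voiced frames.
#' @return A [CycleSequence-class] with at least 12 cycles (the APQ11
#'   shimmer variant needs 11-point windows); fewer cycles raise an error.
#' @export
extractCycles <- function(w, pt) {
  stopifnot(is(w, "Waveform"), is(pt, "PitchTrack"))
  voiced <- pt@f0 > 0
  if (sum(voiced) < 5L) stop("need at least 5 voiced frames to extract cycles")
  x <- w@samples
  n <- length(x)
  fs <- w@fs
  vt <- pt@times[voiced]; vf <- pt@f0[voiced]
  # guide the search with inlier frames only (guards against residual
  # octave errors in the track)
  med <- stats::median(vf)
  inl <- vf > 0.75 * med & vf < 1.33 * med
  if (sum(inl) >= 3L) { vt <- vt[inl]; vf <- vf[inl] }
  periodAt <- function(t) 1 / stats::approx(vt, vf, xout = t, rule = 2)$y
  t_start <- max(vt[1L], 0)
  i_from <- max(1L, as.integer(floor(t_start * fs)))
  T0 <- as.integer(round(periodAt(t_start) * fs))
  i_to <- min(i_from + as.integer(1.5 * T0), n)
  i_peak <- i_from - 1L + which.max(x[i_from:i_to])
  pp <- parabolicPeak(x, i_peak)
  marks <- (i_peak - 1L + pp[1L]) / fs
  t_last_voiced <- vt[length(vt)] + periodAt(vt[length(vt)])
  repeat {
    t_prev <- marks[length(marks)]
    if (t_prev > t_last_voiced) break
    T_loc <- periodAt(t_prev) * fs              # samples
    b <- as.integer(round(t_prev * fs)) + 1L
    W <- as.integer(round(0.9 * T_loc))
    lag_lo <- as.integer(floor(0.8 * T_loc))
    lag_hi <- as.integer(ceiling(1.25 * T_loc))
    if (b + lag_hi + W > n || W < 4L) break
    tmpl <- x[b:(b + W - 1L)]
    e0 <- sum(tmpl^2)
    if (e0 <= 0) break
    lags <- lag_lo:lag_hi
    ncc <- vapply(lags, function(L) {
      seg <- x[(b + L):(b + L + W - 1L)]
      sum(tmpl * seg) / sqrt(e0 * sum(seg^2))
    }, numeric(1))
    j <- which.max(ncc)
    L_star <- lags[j] + parabolicPeak(ncc, j)[1L]
    t_new <- t_prev + L_star / fs
    marks <- c(marks, t_new)
  }
  if (length(marks) < 13L)
    stop("insufficient cycles: found ", max(length(marks) - 1L, 0L),
         ", need at least 12 (APQ11)")
  periods <- diff(marks)
  # per-cycle peak amplitude: interpolated maximum within the cycle
  amps <- vapply(seq_along(periods), function(i) {
    i0 <- max(1L, as.integer(floor(marks[i] * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling(marks[i + 1L] * fs)))
    ip <- i0 - 1L + which.max(x[i0:i1])
    parabolicPeak(x, ip)[2L]
  }, numeric(1))
  new("CycleSequence", marks = marks, periods = periods,
      amplitudes = pmax(amps, .Machine$double.eps))
}
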