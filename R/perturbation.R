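# Jitter and shimmer metric families (the standard voice-report variants)
# and the autocorrelation-based harmonics-to-noise ratio.

#' Jitter metrics of a cycle sequence
#'
#' Five standard variants computed from per-cycle periods `T_i`
#' (`N >= 12` cycles required):
#' \describe{
#'   \item{local}{`mean |T_i - T_(i-1)| / mean(T) * 100` (percent)}
#'   \item{local_abs}{`mean |T_i - T_(i-1)|` (seconds)}
#'   \item{rap}{3-point relative average perturbation (percent)}
#'   \item{ppq5}{5-point period perturbation quotient (percent)}
#'   \item{ddp}{`mean |(T_(i+1)-T_i) - (T_i-T_(i-1))| / mean(T) * 100`;
#'     identically `3 * rap`}
#' }
#'
#' @param c a [CycleSequence-class].
#' @return Named numeric: `jitter_local_pct`, `jitter_local_abs_s`,
#'   `jitter_rap_pct`, `jitter_ppq5_pct`, `jitter_ddp_pct`.
#' @export
jitterMetrics <- function(c) {
  stopifnot(is(c, "CycleSequence"))
  T <- c@periods
  N <- length(T)
  if (N < 12L) stop("insufficient cycles for jitter metrics (need >= 12)")
  mT <- mean(T)
  dT <- abs(diff(T))
  local_abs <- mean(dT)
  rap <- mean(abs(T[2:(N - 1)] -
                  (T[1:(N - 2)] + T[2:(N - 1)] + T[3:N]) / 3)) / mT * 100
  ppq5 <- mean(abs(vapply(3:(N - 2), function(i)
    T[i] - mean(T[(i - 2):(i + 2)]), numeric(1)))) / mT * 100
  ddp <- mean(abs(diff(T, differences = 2))) / mT * 100
  c(jitter_local_pct = local_abs / mT * 100,
    jitter_local_abs_s = local_abs,
    jitter_rap_pct = rap,
    jitter_ppq5_pct = ppq5,
    jitter_ddp_pct = ddp)
}

#' Shimmer metrics of a cycle sequence
#'
#' Six standard variants computed from per-cycle peak amplitudes `A_i`
#' (`N >= 12`, all positive):
#' \describe{
#'   \item{local}{`mean |A_(i+1) - A_i| / mean(A) * 100` (percent)}
#'   \item{local_db}{`mean |20 log10(A_(i+1) / A_i)|` (dB)}
#'   \item{apq3/apq5/apq11}{q-point amplitude perturbation quotients
#'     (percent): mean deviation from the q-point moving average}
#'   \item{dda}{identically `3 * apq3`}
#' }
#'
#' @param c a [CycleSequence-class].
#' @return Named numeric: `shimmer_local_pct`, `shimmer_local_db`,
#'   `shimmer_apq3_pct`, `shimmer_apq5_pct`, `shimmer_apq11_pct`,
#'   `shimmer_dda_pct`.
#' @export
shimmerMetrics <- function(c) {
  stopifnot(is(c, "CycleSequence"))
  A <- c@amplitudes
  N <- length(A)
  if (N < 12L) stop("insufficient cycles for shimmer metrics (need >= 12)")
  if (any(A <= 0)) stop("non-positive cycle amplitude")
  mA <- mean(A)
  apq <- function(q) {
    h <- (q - 1L) %/% 2L
    mean(abs(vapply((h + 1L):(N - h), function(i)
      A[i] - mean(A[(i - h):(i + h)]), numeric(1)))) / mA * 100
  }
  apq3 <- apq(3L)
  c(shimmer_local_pct = mean(abs(diff(A))) / mA * 100,
    shimmer_local_db = mean(abs(20 * log10(A[-1L] / A[-N]))),
    shimmer_apq3_pct = apq3,
    shimmer_apq5_pct = apq(5L),
    shimmer_apq11_pct = apq(11L),
    shimmer_dda_pct = 3 * apq3)
}

#' Harmonics-to-noise ratio (dB)
#'
#' Per voiced frame, the normalized autocorrelation `r` at the pitch lag
#' estimates the fraction of periodic power; the frame HNR is
#' `10 log10(r / (1 - r))` and the returned value is the mean over voiced
#' frames, capped at +40 dB (a perfectly periodic frame has `r -> 1`).
#'
#' @param w a [Waveform-class].
#' @param pt a [PitchTrack-class] of `w` with at least 5 voiced frames.
#' @return HNR estimate in dB.
#' @export
harmonicsToNoiseRatio <- function(w, pt) {
  stopifnot(is(w, "Waveform"), is(pt, "PitchTrack"))
  voiced <- which(pt@f0 > 0)
  if (length(voiced) < 5L) stop("need at least 5 voiced frames for HNR")
  win <- as.integer(round(0.04 * w@fs))
  half <- win %/% 2L
  n <- length(w@samples)
  hnr <- numeric(0)
  for (i in voiced) {
    ctr <- as.integer(round(pt@times[i] * w@fs))
    i0 <- max(1L, ctr - half)
    i1 <- min(n, i0 + win - 1L)
    fr <- w@samples[i0:i1]
    fr <- fr - mean(fr)
    if (sum(fr^2) <= 0) next
    lag <- w@fs / pt@f0[i]
    lag_i <- as.integer(round(lag))
    if (lag_i + 2L > length(fr) - 1L) next
    r <- normalizedAutocorr(fr, min(lag_i + 2L, length(fr) - 1L))
    # refine around the nominal pitch lag
    lo <- max(1L, lag_i - 2L); hi <- min(length(r), lag_i + 2L)
    j <- lo - 1L + which.max(r[lo:hi])
    rp <- parabolicPeak(r, j)[2L]
    rp <- min(max(rp, 1e-6), 1 - 1e-6)
    hnr <- c(hnr, 10 * log10(rp / (1 - rp)))
  }
  if (!length(hnr)) stop("no usable voiced frame for HNR")
  min(mean(pmin(hnr, 40)), 40)
}
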