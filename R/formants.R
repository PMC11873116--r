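# Formant estimation by linear-prediction root solving.

#' Formant frequency summary (f1--f4 mean and SD)
#'
#' Frame-wise LPC analysis (25 ms Hamming-windowed frames, 10 ms hop,
#' pre-emphasis 0.97, order 12 at an internal analysis rate of at most
#' ~11 kHz): the poles of the prediction polynomial yield candidate
#' formants at `angle * fs / (2 pi)` with bandwidth `-(fs / pi) ln|pole|`.
#' Candidates with `250 Hz < f < fs/2 - 50 Hz` and bandwidth < 400 Hz are
#' kept and the lowest four assigned as f1--f4 per frame (the 250 Hz
#' floor rejects low spectral-tilt poles; no vowel has F1 below it).
#'
#' @param w a voiced [Waveform-class], `sampleRate(w) >= 8000`.
#' @return Named numeric of length 8 (`f1_mean_hz`, `f1_sd_hz`, ...,
#'   `f4_sd_hz`), with attribute `partial = TRUE` when more than half of
#'   the frames yielded fewer than four candidates.
#' @export
formantSummary <- function(w) {
  stopifnot(is(w, "Waveform"))
  if (w@fs < 8000) stop("formant analysis requires fs >= 8000 Hz")
  if (w@fs > 12000) w <- decimateWaveform(w, round(w@fs / 11025))
  fs <- w@fs
  x <- c(w@samples[1L], diff(w@samples) + (1 - 0.97) * w@samples[-length(w@samples)])
  win <- as.integer(round(0.025 * fs))
  hop <- as.integer(round(0.010 * fs))
  starts <- frameStarts(length(x), win, hop)
  hw <- hammingWindow(win)
  p <- if (fs > 10000) 12L else 10L
  fmat <- matrix(NA_real_, nrow = length(starts), ncol = 4L)
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + win - 1L)] * hw
    r <- biasedAutocorr(fr, p)
    if (r[1L] <= 0) next
    ld <- levinsonDurbin(r, p)
    # polyroot() solves in the z^-1 variable; poles are the reciprocals
    z <- 1 / polyroot(c(1, -ld$a))
    ang <- Arg(z)
    keep <- ang > 0
    f <- ang[keep] * fs / (2 * pi)
    bw <- -(fs / pi) * log(Mod(z[keep]))
    ok <- f > 250 & f < fs / 2 - 50 & bw < 400
    cand <- sort(f[ok])
    if (length(cand) >= 1L)
      fmat[i, seq_len(min(4L, length(cand)))] <- cand[seq_len(min(4L, length(cand)))]
  }
  full <- rowSums(!is.na(fmat)) == 4L
  partial <- mean(full) < 0.5
  out <- numeric(8L)
  names(out) <- as.vector(t(outer(paste0("f", 1:4),
                                  c("_mean_hz", "_sd_hz"), paste0)))
  for (k in 1:4) {
    v <- fmat[, k]
    v <- v[!is.na(v)]
    out[2L * k - 1L] <- if (length(v)) mean(v) else NA_real_
    out[2L * k] <- if (length(v) > 1L) stats::sd(v) else NA_real_
  }
  attr(out, "partial") <- partial
  out
}
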