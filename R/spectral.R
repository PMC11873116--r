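# Windowed autoregressive spectral analysis: framing, Levinson-Durbin
# solution of the Yule-Walker equations, log-area-ratio and cepstral
# transforms of the AR model, and mel-frequency cepstral coefficients.
# Sign convention throughout: A(z) = 1 - sum_{k=1}^{p} a_k z^{-k}.

#' Slice a waveform into contiguous analysis frames
#'
#' No-padding framing: frame count is `floor((n - win) / hop) + 1`; frames
#' are raw contiguous sample windows (no taper — the AR analysis operates
#' on untapered samples). The default 256-sample window with 50% overlap
#' corresponds to 32 ms at an 8 kHz analysis rate.
#'
#' @param w a [Waveform-class] with at least `win` samples.
#' @param win window length in samples (default 256).
#' @param overlap fractional overlap (default 0.5, i.e. hop = win/2).
#' @return List with `frames` (win x count matrix, one frame per column),
#'   `win`, `hop`, `fs`.
#' @export
frameSignal <- function(w, win = 256L, overlap = 0.5) {
  stopifnot(is(w, "Waveform"))
  win <- as.integer(win)
  hop <- as.integer(round(win * (1 - overlap)))
  starts <- frameStarts(length(w@samples), win, hop)
  frames <- vapply(starts, function(s) w@samples[s:(s + win - 1L)],
                   numeric(win))
  list(frames = matrix(frames, nrow = win), win = win, hop = hop, fs = w@fs)
}

#' Levinson-Durbin recursion
#'
#' Solves the order-`p` Yule-Walker system for the autocorrelation lags
#' `r[0..p]`, returning the prediction coefficients `a` (convention
#' `A(z) = 1 - sum a_k z^-k`, so `x_t ~ sum a_k x_(t-k)`), the reflection
#' (partial correlation) coefficients `k`, and the final prediction error
#' power. With a valid (biased-estimator) autocorrelation, `|k_i| < 1` and
#' the error is non-increasing in the order.
#'
#' @param r numeric vector of autocorrelation lags `0..p` (at least),
#'   `r[1] > 0`.
#' @param p model order (default 10).
#' @return List with `a` (length p), `k` (length p), `err` (scalar), and
#'   `stable` (FALSE when any `|k_i| >= 1`).
#' @examples
#' levinsonDurbin(c(1, 0.5), p = 1)  # a = k = 0.5, err = 0.75
#' @export
levinsonDurbin <- function(r, p = 10L) {
  if (length(r) < p + 1L) stop("need autocorrelation lags 0..p")
  if (r[1L] <= 0) stop("degenerate autocorrelation: r[0] must be > 0")
  a <- numeric(p)
  k <- numeric(p)
  err <- r[1L]
  for (m in seq_len(p)) {
    acc <- r[m + 1L]
    if (m > 1L) acc <- acc - sum(a[1:(m - 1L)] * r[m:2L])
    km <- acc / err
    k[m] <- km
    a_new <- a
    a_new[m] <- km
    if (m > 1L) a_new[1:(m - 1L)] <- a[1:(m - 1L)] - km * a[(m - 1L):1L]
    a <- a_new
    err <- err * (1 - km^2)
  }
  list(a = a, k = k, err = err, stable = all(abs(k) < 1))
}

#' Reflection coefficients to log-area ratios
#'
#' `g_i = ln((1 + k_i) / (1 - k_i))` — finite whenever `|k_i| < 1`, and an
#' odd function of `k`.
#'
#' @param k reflection coefficients with `|k_i| < 1`.
#' @return LAR vector of the same length.
#' @seealso [larToParcor()]
#' @export
parcorToLar <- function(k) {
  if (any(abs(k) >= 1)) stop("|k| >= 1: reflection coefficients must lie in (-1, 1)")
  log((1 + k) / (1 - k))
}

#' @rdname parcorToLar
#' @param g log-area ratios.
#' @export
larToParcor <- function(g) (exp(g) - 1) / (exp(g) + 1)

#' LPC coefficients to cepstral coefficients (LPCC)
#'
#' Recursion for the cepstrum of the all-pole model `1 / A(z)` with
#' `A(z) = 1 - sum a_k z^-k`:
#' `c_1 = a_1`; `c_n = a_n + sum_{k=1}^{n-1} (k / n) c_k a_(n-k)`.
#'
#' @param a LPC coefficient vector (length p).
#' @param p number of cepstral coefficients to return (default
#'   `length(a)`).
#' @return LPCC vector `c_1..c_p`.
#' @export
lpcToCepstrum <- function(a, p = length(a)) {
  cc <- numeric(p)
  if (p == 0L) return(cc)
  get_a <- function(n) if (n <= length(a)) a[n] else 0
  cc[1L] <- get_a(1L)
  if (p > 1L) for (n in 2:p) {
    s <- 0
    for (k in 1:(n - 1L)) s <- s + (k / n) * cc[k] * get_a(n - k)
    cc[n] <- get_a(n) + s
  }
  cc
}

# Triangular mel filterbank: n_filt height-1 triangles equally spaced on
# the mel axis between 0 and fs/2, evaluated at the n_bins FFT bin
# frequencies. Returns n_bins x n_filt weights.
melFilterbank <- function(n_filt, n_bins, fs, nfft) {
  f_bins <- (seq_len(n_bins) - 1L) * fs / nfft
  mel_pts <- seq(hzToMel(0), hzToMel(fs / 2), length.out = n_filt + 2L)
  f_pts <- melToHz(mel_pts)
  fb <- matrix(0, nrow = n_bins, ncol = n_filt)
  for (m in seq_len(n_filt)) {
    lo <- f_pts[m]; ctr <- f_pts[m + 1L]; hi <- f_pts[m + 2L]
    up <- (f_bins - lo) / (ctr - lo)
    down <- (hi - f_bins) / (hi - ctr)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel-frequency cepstral coefficients of one frame
#'
#' Hann-windowed power spectrum, triangular mel filterbank (`n_filt`
#' height-1 filters, 0 to fs/2, equal mel spacing), floored natural-log
#' energies, orthonormal type-II DCT; coefficients `1..n_coef` are
#' returned (`c_0`, which carries the overall gain, is excluded, so the
#' output is invariant to global gain).
#'
#' @param frame numeric sample vector (length >= 64).
#' @param fs sampling rate, Hz.
#' @param n_coef number of coefficients (default 10).
#' @param n_filt number of mel filters (default 26).
#' @return Numeric vector of length `n_coef`.
#' @export
mfccFrame <- function(frame, fs, n_coef = 10L, n_filt = 26L) {
  n <- length(frame)
  if (n < 64L) stop("frame too short for MFCC (need >= 64 samples)")
  nfft <- 2^ceiling(log2(n))
  xw <- frame * hannWindow(n)
  X <- stats::fft(c(xw, numeric(nfft - n)))
  pow <- Mod(X[1:(nfft / 2 + 1L)])^2 / nfft
  fb <- melFilterbank(n_filt, nfft / 2 + 1L, fs, nfft)
  e <- as.numeric(crossprod(fb, pow))
  loge <- log(pmax(e, 1e-12))
  m <- seq_len(n_filt)
  k <- seq_len(n_coef)
  dct <- sqrt(2 / n_filt) * cos(pi * outer(k, (2 * m - 1) / (2 * n_filt)))
  as.numeric(dct %*% loge)
}

#' Spectral coefficient tracks of a recording
#'
#' Frames the waveform ([frameSignal()]) and computes one coefficient
#' vector per frame for the requested representation: `lpc` (AR(10)
#' prediction coefficients via [levinsonDurbin()] on the biased
#' autocorrelation), `lar` (log-area ratios of the reflection
#' coefficients), `lpcc` (cepstral recursion of the LPC model) or `mfcc`
#' ([mfccFrame()]). Silent frames yield zero coefficient vectors (MFCC:
#' floored log energies).
#'
#' @param w a [Waveform-class].
#' @param kind one of `"lpc"`, `"lar"`, `"lpcc"`, `"mfcc"`.
#' @param p coefficient order (default 10).
#' @param win,overlap framing parameters, see [frameSignal()].
#' @return frames x p numeric matrix.
#' @export
spectralCoefficients <- function(w, kind = c("lpc", "lar", "lpcc", "mfcc"),
                                 p = 10L, win = 256L, overlap = 0.5) {
  kind <- match.arg(kind)
  fm <- frameSignal(w, win = win, overlap = overlap)
  n_fr <- ncol(fm$frames)
  out <- matrix(0, nrow = n_fr, ncol = p)
  for (i in seq_len(n_fr)) {
    fr <- fm$frames[, i]
    if (kind == "mfcc") {
      out[i, ] <- mfccFrame(fr, fm$fs, n_coef = p)
    } else {
      r <- biasedAutocorr(fr, p)
      if (r[1L] <= 0) next
      ld <- levinsonDurbin(r, p)
      out[i, ] <- switch(kind,
        lpc = ld$a,
        lar = parcorToLar(pmin(pmax(ld$k, -1 + 1e-12), 1 - 1e-12)),
        lpcc = lpcToCepstrum(ld$a, p))
    }
  }
  colnames(out) <- paste0(kind, seq_len(p))
  out
}

#' Summarize a coefficient track into per-recording mean and variance
#'
#' @param track frames x p coefficient matrix (>= 2 frames).
#' @param subject_id subject identifier.
#' @param kind representation label.
#' @return A [SpectralSummary-class] with element-wise mean and sample
#'   variance across frames.
#' @export
summarizeCoefficients <- function(track, subject_id = "subject",
                                  kind = "lpc") {
  if (nrow(track) < 2L) stop("variance undefined: need at least 2 frames")
  new("SpectralSummary", kind = kind,
      mean_vec = colMeans(track),
      var_vec = apply(track, 2L, stats::var),
      subject_id = subject_id)
}

#' Combine a spectral summary with a phonation feature vector
#'
#' Concatenates one statistic (mean or variance vector) of a spectral
#' representation with the 23-entry phonation vector of the same subject
#' (10 + 23 = 33 entries), in a stable documented order.
#'
#' @param s a [SpectralSummary-class].
#' @param pmf phonation feature vector from [phonationFeatures()].
#' @param stat `"var"` (default, the better-performing statistic) or
#'   `"mean"`.
#' @return Named numeric of length 33 with attribute `subject_id`.
#' @export
combineFeatures <- function(s, pmf, stat = c("var", "mean")) {
  stat <- match.arg(stat)
  stopifnot(is(s, "SpectralSummary"))
  sid <- attr(pmf, "subject_id")
  if (!is.null(sid) && !identical(sid, s@subject_id))
    stop("subject mismatch: '", s@subject_id, "' vs '", sid, "'")
  vec <- if (stat == "var") s@var_vec else s@mean_vec
  names(vec) <- paste0(s@kind, "_", stat, seq_along(vec))
  out <- c(vec, pmf[phonationFeatureNames()])
  attr(out, "subject_id") <- s@subject_id
  out
}
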