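# Internal DSP primitives: FIR design (windowed sinc), zero-phase FIR
# filtering via FFT convolution, FFT resampling, framing, windows and
# normalized autocorrelation. No external DSP dependency is available in
# this stack, so these are written from first principles and are the
# subject of the package's oracle-equivalence tests.

hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

hammingWindow <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

blackmanWindow <- function(n) {
  k <- (seq_len(n) - 1L) / (n - 1L)
  0.42 - 0.5 * cos(2 * pi * k) + 0.08 * cos(4 * pi * k)
}

# Windowed-sinc low-pass FIR, cutoff in Hz, Blackman window (~74 dB
# stopband). n_taps forced odd so the filter is exactly linear phase with
# integer group delay.
firLowpass <- function(cutoff, fs, n_taps) {
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  m <- (n_taps - 1L) / 2L
  k <- seq(-m, m)
  fc <- cutoff / fs
  h <- 2 * fc * sinc(2 * fc * k) * blackmanWindow(n_taps)
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Band-pass as difference of two low-passes; unity gain at band center.
firBandpass <- function(low, high, fs, n_taps) {
  h <- firLowpass(high, fs, n_taps) - firLowpass(low, fs, n_taps)
  fc <- (low + high) / 2
  m <- (length(h) - 1L) / 2L
  k <- seq(-m, m)
  g <- abs(sum(h * exp(-2i * pi * fc / fs * k)))
  h / g
}

# Centered ("same") convolution via FFT; with a symmetric odd-length FIR
# this is zero-phase filtering (the linear-phase delay is removed).
filterFIR <- function(x, h) {
  n <- length(x)
  m <- (length(h) - 1L) / 2L
  nfft <- 2^ceiling(log2(n + length(h) - 1L))
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[(m + 1L):(m + n)]
}

# Fourier-domain resampling (assumes the signal is band-limited below the
# target Nyquist, which the channel/anti-alias filters guarantee here).
resampleFFT <- function(x, fs_in, fs_out) {
  n <- length(x)
  n_out <- round(n * fs_out / fs_in)
  X <- stats::fft(x)
  Y <- complex(n_out)
  keep <- min(n, n_out)
  h <- floor(keep / 2)
  Y[1:(h + 1L)] <- X[1:(h + 1L)]
  if (h > 0) Y[(n_out - h + 1L):n_out] <- X[(n - h + 1L):n]
  # inverse DFT of length n_out, amplitude preserved relative to x
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# Frame start indices for a no-padding sliding window:
# count = floor((n - win) / hop) + 1.
frameStarts <- function(n, win, hop) {
  if (n < win) stop("signal shorter than one analysis window (", n, " < ", win, ")")
  count <- floor((n - win) / hop) + 1L
  1L + (seq_len(count) - 1L) * hop
}

# Biased autocorrelation lags 0..p (divide by n): guarantees |k| < 1 in the
# Levinson recursion.
biasedAutocorr <- function(x, p) {
  n <- length(x)
  r <- numeric(p + 1L)
  for (k in 0:p) r[k + 1L] <- sum(x[1:(n - k)] * x[(k + 1L):n]) / n
  r
}

# Full normalized autocorrelation of one frame for lags 1..max_lag, where
# each lag is normalized by the energies of the two overlapping segments:
#   r(tau) = sum_t x_t x_{t+tau} / sqrt(sum_{t<=N-tau} x_t^2 * sum_{t>tau} x_t^2)
# This is exactly 1 for a perfectly periodic frame at its period lag.
normalizedAutocorr <- function(x, max_lag) {
  n <- length(x)
  max_lag <- min(max_lag, n - 1L)
  nfft <- 2^ceiling(log2(2L * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  ac <- Re(stats::fft(X * Conj(X), inverse = TRUE))[1:(max_lag + 1L)] / nfft
  cs <- cumsum(x^2)
  lags <- seq_len(max_lag)
  d1 <- cs[n - lags]
  d2 <- cs[n] - cs[lags]
  den <- sqrt(pmax(d1 * d2, .Machine$double.eps))
  r <- ac[lags + 1L] / den
  pmin(pmax(r, -1), 1)
}

# Parabolic interpolation of a local maximum at integer index i of y;
# returns c(offset, value) with offset in (-0.5, 0.5).
parabolicPeak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(c(0, y[i]))
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  den <- a - 2 * b + c
  if (abs(den) < .Machine$double.eps) return(c(0, b))
  off <- 0.5 * (a - c) / den
  off <- max(min(off, 0.5), -0.5)
  c(off, b - 0.25 * (a - c) * off)
}

# Bilinear resampling of a matrix to nr x nc (used for image rendering and
# CNN input preparation).
resizeBilinear <- function(m, nr, nc) {
  r0 <- nrow(m); c0 <- ncol(m)
  ri <- if (nr == 1L) rep(1, 1) else seq(1, r0, length.out = nr)
  ci <- if (nc == 1L) rep(1, 1) else seq(1, c0, length.out = nc)
  rf <- floor(ri); rc <- pmin(rf + 1L, r0); ra <- ri - rf
  cf <- floor(ci); cc <- pmin(cf + 1L, c0); ca <- ci - cf
  top <- m[rf, cf, drop = FALSE] * outer(1 - ra, 1 - ca) +
         m[rf, cc, drop = FALSE] * outer(1 - ra, ca)
  bot <- m[rc, cf, drop = FALSE] * outer(ra, 1 - ca) +
         m[rc, cc, drop = FALSE] * outer(ra, ca)
  top + bot
}

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic fan-out of one global seed to per-stage seeds (kept below
# 2^31 so it is always a valid integer seed).
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
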