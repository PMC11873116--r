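# Shared fixtures: tone generators, independent oracles (kept straight-line
# and separate from the implementation paths they check).

toneWave <- function(freq, fs, dur = 1, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * seq_len(round(dur * fs)) / fs), fs)
}

rmsOf <- function(w) sqrt(mean(samples(w)^2))

dbRel <- function(a, b) 20 * log10(a / b)

# Step-up recursion: reflection coefficients -> AR coefficients
# (convention A(z) = 1 - sum a_k z^-k).
reflectionToAR <- function(k) {
  a <- numeric(0)
  for (m in seq_along(k)) {
    a_new <- c(a, k[m])
    if (m > 1L) a_new[1:(m - 1L)] <- a - k[m] * rev(a)
    a <- a_new
  }
  a
}

# Exact autocovariance lags 0..p of a stable AR(p) process with unit
# innovation variance, by solving the extended Yule-Walker system.
arAutocorr <- function(a) {
  p <- length(a)
  A <- matrix(0, p + 1L, p + 1L)
  for (i in 0:p) {
    A[i + 1L, i + 1L] <- A[i + 1L, i + 1L] + 1
    for (j in 1:p) {
      idx <- abs(i - j)
      A[i + 1L, idx + 1L] <- A[i + 1L, idx + 1L] - a[j]
    }
  }
  solve(A, c(1, numeric(p)))
}

# Random stable AR(p) via conjugate pole pairs with bounded radius and a
# minimum angular separation (keeps the associated Toeplitz systems well
# conditioned so the 1e-8 agreement bound is meaningful rather than
# dominated by solver round-off).
randomStableAR <- function(p = 10L, rmax = 0.9, minsep = 0.3) {
  stopifnot(p %% 2L == 0L)
  npair <- p / 2L
  repeat {
    th <- sort(stats::runif(npair, 0.15, pi - 0.15))
    if (npair == 1L || min(diff(th)) >= minsep) break
  }
  r <- stats::runif(npair, 0.3, rmax)
  coef <- 1
  for (i in seq_len(npair))
    coef <- convolve(coef, rev(c(1, -2 * r[i] * cos(th[i]), r[i]^2)),
                     type = "open")
  -coef[-1L]
}

# FFT cepstrum oracle: for a minimum-phase all-pole model 1/A(z), the
# complex cepstrum at n >= 1 is twice the real cepstrum of the magnitude.
fftCepstrumOracle <- function(a, p = 10L, N = 4096L) {
  Aw <- stats::fft(c(1, -a, numeric(N - length(a) - 1L)))
  creal <- Re(stats::fft(-log(Mod(Aw)), inverse = TRUE)) / N
  2 * creal[2:(p + 1L)]
}

# Straight-line MFCC oracle: direct evaluation of the definition with
# explicit loops (independent of the package's vectorized path).
mfccOracle <- function(frame, fs, n_coef = 10L, n_filt = 26L) {
  n <- length(frame)
  nfft <- 2^ceiling(log2(n))
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- stats::fft(c(frame * h, numeric(nfft - n)))
  pow <- Mod(X[1:(nfft / 2 + 1L)])^2 / nfft
  m2h <- function(m) 700 * (10^(m / 2595) - 1)
  h2m <- function(f) 2595 * log10(1 + f / 700)
  mel_pts <- seq(0, h2m(fs / 2), length.out = n_filt + 2L)
  f_pts <- m2h(mel_pts)
  loge <- numeric(n_filt)
  for (m in seq_len(n_filt)) {
    e <- 0
    for (b in seq_along(pow)) {
      fb <- (b - 1) * fs / nfft
      wgt <- 0
      if (fb >= f_pts[m] && fb <= f_pts[m + 1L])
        wgt <- (fb - f_pts[m]) / (f_pts[m + 1L] - f_pts[m])
      else if (fb > f_pts[m + 1L] && fb <= f_pts[m + 2L])
        wgt <- (f_pts[m + 2L] - fb) / (f_pts[m + 2L] - f_pts[m + 1L])
      e <- e + wgt * pow[b]
    }
    loge[m] <- log(max(e, 1e-12))
  }
  out <- numeric(n_coef)
  for (k in seq_len(n_coef)) {
    s <- 0
    for (m in seq_len(n_filt))
      s <- s + loge[m] * cos(pi * k * (2 * m - 1) / (2 * n_filt))
    out[k] <- sqrt(2 / n_filt) * s
  }
  out
}

# Naive frame-count oracle (explicit loop).
naiveFrameCount <- function(n, win, hop) {
  count <- 0L
  s <- 1L
  while (s + win - 1L <= n) {
    count <- count + 1L
    s <- s + hop
  }
  count
}
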