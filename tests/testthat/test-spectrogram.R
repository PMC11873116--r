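# Spectrograms: mel scale mapping, STFT recipes, rendering, group
# difference maps.

test_that("mel scale follows the 2595 log10 form with exact inverse", {
  expect_equal(hzToMel(0), 0)
  expect_equal(hzToMel(700), 2595 * log10(2))
  expect_lt(abs(hzToMel(1000) - 1000), 0.1)  # near-identity at 1 kHz
  f <- seq(0, 4400, by = 10)
  expect_true(all(diff(hzToMel(f)) > 0))
  back <- melToHz(hzToMel(f))
  expect_lt(max(abs(back - f) / pmax(f, 1)), 1e-9)
  expect_error(hzToMel(-1), ">= 0")
})

test_that("linear spectrogram reproduces the printed frame count", {
  w <- waveform(samples(toneWave(1000, 8820, dur = 1.5, amp = 0.8)), 8820)
  m <- linearSpectrogram(w)
  expect_equal(nrow(m@values), 48L)   # 1.5 s at 8820 Hz
  expect_equal(ncol(m@values), 513L)  # NFFT/2 + 1
  expect_identical(max(m@values), 0)
  # pure tone concentrates at the bin nearest 1 kHz in every frame
  peak_bin <- apply(m@values, 1L, which.max)
  expect_true(all(peak_bin == which.min(abs(m@freqs - 1000))))
  expect_error(linearSpectrogram(waveform(rep(0.1, 512), 8820)), "short")
})

test_that("mel spectrogram reproduces the printed frame count", {
  w <- toneWave(150, 8820, dur = 1.5, amp = 0.8)
  m <- melSpectrogram(w)
  expect_equal(nrow(m@values), 260L)  # hop 51, center padding
  expect_equal(ncol(m@values), 256L)
  expect_identical(max(m@values), 0)
  expect_error(melSpectrogram(waveform(rep(0.1, 400), 8820)), "short")
})

test_that("STFT satisfies a Parseval-style power identity", {
  set.seed(4)
  w <- waveform(stats::rnorm(8192) / 5, 8000)
  st <- stft(w, win = 1024L, hop = 256L, nfft = 1024L)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:1023) / 1023)
  starts <- pdvoice:::frameStarts(8192, 1024L, 256L)
  p_time <- sum(vapply(starts, function(s)
    sum((samples(w)[s:(s + 1023)] * h)^2), numeric(1)))
  m2 <- Mod(st$S)^2
  p_freq <- sum(2 * m2[, 2:512], m2[, 1], m2[, 513]) / 1024
  expect_lt(abs(p_freq - p_time) / p_time, 0.01)
})

test_that("slow F0 tremor appears as a ripple at the tremor rate", {
  sp <- vowelSpec(duration = 4, f0 = 150, jitter_pct = 0.3, shimmer_pct = 2,
                  tremor_rate = 5, tremor_depth = 0.02, hnr_db = 25)
  w <- decimateWaveform(synthesizeVowel(sp, 44100, seed = 3), 5)
  m <- melSpectrogram(w)
  band <- which(m@freqs >= hzToMel(100) & m@freqs <= hzToMel(220))
  trk <- m@freqs[band[apply(m@values[, band], 1L, which.max)]]
  trk <- trk - mean(trk)
  n <- length(trk)
  han <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
  N <- 8192L
  spec <- Mod(stats::fft(c(trk * han, numeric(N - n))))
  fgrid <- (0:(N - 1)) * (8820 / 51) / N
  sel <- fgrid > 1 & fgrid < 20
  peak <- fgrid[sel][which.max(spec[sel])]
  expect_lt(abs(peak - 5), 0.5)
})

test_that("image rendering is deterministic with fixed geometry", {
  w <- toneWave(150, 8820, dur = 1.5, amp = 0.8)
  m <- melSpectrogram(w)
  img1 <- renderSpectrogramImage(m, subject_id = "S1")
  img2 <- renderSpectrogramImage(m, subject_id = "S1")
  expect_equal(dim(img1@pixels), c(600L, 600L, 3L))
  expect_identical(img1@pixels, img2@pixels)
  expect_identical(img1@colormap, "viridis")
  path <- tempfile(fileext = ".png")
  writeSpectrogramImage(img1, path)
  expect_true(file.exists(path) && file.size(path) > 0)
  # a constant matrix renders as a single color
  cm <- new("SpectrogramMatrix", values = matrix(0, 10, 10),
            times = 1:10 / 10, freqs = 1:10, scale = "linear", fs = 8000)
  cimg <- renderSpectrogramImage(cm)
  expect_equal(length(unique(as.vector(cimg@pixels[, , 1]))), 1L)
})

test_that("group-average difference maps localize an F0 shift", {
  mk <- function(f0, s) melSpectrogram(toneWave(f0, 8820, dur = 1.5, amp = 0.8))
  pd <- list(mk(123), mk(124))
  hc <- list(mk(116), mk(117))
  d <- averageSpectrogramDifference(pd, hc)
  band_pd <- which(attr(d, "freqs") >= hzToMel(120) & attr(d, "freqs") <= hzToMel(128))
  expect_gt(mean(colMeans(d)[band_pd]), 0)
  expect_equal(max(abs(averageSpectrogramDifference(pd, pd))), 0)
  expect_error(averageSpectrogramDifference(pd, list()), "non-empty")
  short <- list(melSpectrogram(toneWave(116, 8820, dur = 1, amp = 0.8)))
  expect_error(averageSpectrogramDifference(pd, short), "mismatch")
})
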