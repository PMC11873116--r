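# Windowed AR spectral features: framing, Levinson-Durbin, LAR, LPCC,
# MFCC, summaries and combination.

test_that("frame counts follow the no-padding closed form", {
  # 3.3 s and 6.8 s at 8 kHz: the two average-duration scenarios
  expect_equal(ncol(frameSignal(waveform(rep(0.1, 26400), 8000))$frames), 205L)
  expect_equal(ncol(frameSignal(waveform(rep(0.1, 54400), 8000))$frames), 424L)
  expect_equal(ncol(frameSignal(waveform(rep(0.1, 256), 8000))$frames), 1L)
  expect_error(frameSignal(waveform(rep(0.1, 255), 8000)), "shorter")
  set.seed(3)
  for (i in 1:30) {
    n <- sample(300:20000, 1)
    win <- sample(c(64, 128, 256, 512), 1)
    hop <- sample(c(32, 64, 128, 200), 1)
    expect_equal(length(frameStarts <- pdvoice:::frameStarts(n, win, hop)),
                 naiveFrameCount(n, win, hop))
  }
})

test_that("Levinson-Durbin solves Yule-Walker exactly", {
  ld0 <- levinsonDurbin(c(1, rep(0, 10)), 10)
  expect_equal(ld0$a, rep(0, 10))
  expect_equal(ld0$err, 1)
  ld1 <- levinsonDurbin(c(1, 0.5), 1)
  expect_equal(ld1$a, 0.5)
  expect_equal(ld1$k, 0.5)
  expect_equal(ld1$err, 0.75)
  expect_error(levinsonDurbin(c(0, 0.5), 1), "degenerate")
  set.seed(10)
  worst <- 0
  for (i in 1:100) {
    a_true <- randomStableAR(10)
    r <- arAutocorr(a_true)
    ld <- levinsonDurbin(r, 10)
    a_direct <- solve(stats::toeplitz(r[1:10]), r[2:11])
    worst <- max(worst, max(abs(ld$a - a_direct)))
    expect_true(all(abs(ld$k) < 1))
    expect_gte(ld$err, 0)
  }
  expect_lt(worst, 1e-8)
})

test_that("log-area-ratio transform and its inverse are exact", {
  expect_equal(parcorToLar(0), 0)
  expect_equal(parcorToLar(0.5), log(3))
  k <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(parcorToLar(-k), -parcorToLar(k))
  expect_lt(max(abs(larToParcor(parcorToLar(k)) - k)), 1e-12)
  expect_error(parcorToLar(c(0.2, 1)), "k")
})

test_that("LPCC recursion matches closed form and FFT cepstrum oracle", {
  expect_equal(lpcToCepstrum(rep(0, 10)), rep(0, 10))
  alpha <- 0.5
  cc <- lpcToCepstrum(c(alpha, rep(0, 9)), 3)
  expect_equal(cc, alpha^(1:3) / (1:3))
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    a <- randomStableAR(10)
    worst <- max(worst, max(abs(lpcToCepstrum(a, 10) - fftCepstrumOracle(a))))
  }
  expect_lt(worst, 1e-6)
})

test_that("MFCC is gain-invariant and matches the straight-line oracle", {
  set.seed(12)
  fr <- stats::rnorm(256)
  expect_lt(max(abs(mfccFrame(fr, 8820) - mfccFrame(0.1 * fr, 8820))), 1e-9)
  t1 <- samples(toneWave(1000, 8820, dur = 256 / 8820))[1:256]
  t2 <- samples(toneWave(2000, 8820, dur = 256 / 8820))[1:256]
  expect_gt(sqrt(sum((mfccFrame(t1, 8820) - mfccFrame(t2, 8820))^2)), 0)
  # synthetic vowel frame against the independent loop implementation
  sp <- vowelSpec(duration = 1.5, f0 = 140, hnr_db = 20)
  w <- decimateWaveform(synthesizeVowel(sp, 44100, seed = 5), 5)
  fr_v <- samples(w)[4001:4256]
  expect_lt(max(abs(mfccFrame(fr_v, 8820) - mfccOracle(fr_v, 8820))), 1e-9)
  expect_error(mfccFrame(fr_v[1:32], 8820), "short")
  # silent frame stays finite via the log floor
  expect_true(all(is.finite(mfccFrame(numeric(256), 8820))))
})

test_that("coefficient summaries compute sample mean and variance", {
  trk <- matrix(c(0, 2), nrow = 2, ncol = 10)
  s <- summarizeCoefficients(trk, "S1", "lpcc")
  expect_equal(unname(s@mean_vec), rep(1, 10))
  expect_equal(unname(s@var_vec), rep(2, 10))
  expect_equal(unname(summarizeCoefficients(matrix(0.3, 5, 10), "S1", "lpc")@var_vec),
               rep(0, 10))
  expect_error(summarizeCoefficients(matrix(1, 1, 10), "S1", "lpc"),
               "2 frames")
})

test_that("tremor inflates coefficient variance relative to stationarity", {
  stat_w <- decimateWaveform(synthesizeVowel(
    vowelSpec(duration = 2, f0 = 150, tremor_depth = 0, hnr_db = 25),
    44100, seed = 21), 5)
  trem_w <- decimateWaveform(synthesizeVowel(
    vowelSpec(duration = 2, f0 = 150, tremor_rate = 5, tremor_depth = 0.04,
              hnr_db = 25), 44100, seed = 21), 5)
  v_stat <- summarizeCoefficients(spectralCoefficients(stat_w, "mfcc"),
                                  "a", "mfcc")@var_vec
  v_trem <- summarizeCoefficients(spectralCoefficients(trem_w, "mfcc"),
                                  "b", "mfcc")@var_vec
  expect_gt(sqrt(sum(v_trem^2)), sqrt(sum(v_stat^2)))
})

test_that("combined feature vectors concatenate to length 33", {
  sp <- vowelSpec(duration = 1.6, f0 = 150, hnr_db = 20)
  w <- decimateWaveform(synthesizeVowel(sp, 44100, seed = 8), 5)
  pmf <- phonationFeatures(w, "S9")
  ss <- summarizeCoefficients(spectralCoefficients(w, "mfcc"), "S9", "mfcc")
  cv <- combineFeatures(ss, pmf, stat = "var")
  expect_length(cv, 33L)
  expect_identical(names(cv)[1:10], paste0("mfcc_var", 1:10))
  expect_identical(names(cv)[11:33], phonationFeatureNames())
  cv2 <- combineFeatures(ss, pmf, stat = "var")
  expect_identical(cv, cv2)
  ss_other <- summarizeCoefficients(spectralCoefficients(w, "mfcc"),
                                    "OTHER", "mfcc")
  expect_error(combineFeatures(ss_other, pmf), "mismatch")
})
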