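# Phonation features: pitch, cycles, jitter/shimmer families, HNR,
# formants and the 23-entry vector.

test_that("pitch tracking is exact on a pure sine and rejects noise", {
  w <- toneWave(150, 8000, dur = 2, amp = 0.9)
  pt <- trackPitch(w)
  f0v <- pt@f0[pt@f0 > 0]
  expect_gt(length(f0v), 0)
  expect_true(all(abs(f0v - 150) <= 0.5))
  for (s in 1:3) {
    set.seed(s)
    ptn <- trackPitch(waveform(stats::rnorm(16000) / 5, 8000))
    expect_gte(mean(ptn@f0 == 0), 0.9)
  }
  expect_error(trackPitch(waveform(stats::rnorm(100) / 5, 8000)), "short")
})

test_that("clean synthetic vowel F0 is recovered within 2 Hz", {
  sp <- vowelSpec(duration = 2, f0 = 192, jitter_pct = 0.3, shimmer_pct = 2,
                  hnr_db = 25)
  w <- synthesizeVowel(sp, fs = 44100, seed = 6)
  pt <- trackPitch(w)
  expect_lt(abs(mean(pt@f0[pt@f0 > 0]) - 192), 2)
})

test_that("cycle extraction recovers equal periods of a periodic signal", {
  w <- toneWave(100, 8000, dur = 1.5, amp = 0.9)
  cyc <- extractCycles(w, trackPitch(w))
  n <- length(cyc@periods)
  expect_gte(n, 145L)
  expect_lte(n, 150L)
  expect_lt(max(cyc@periods) - min(cyc@periods), 1 / 8000)
})

test_that("too few cycles raise an insufficient-cycles error", {
  w <- toneWave(100, 8000, dur = 0.13, amp = 0.9)  # ~12 periods, edges lost
  expect_error(extractCycles(w, suppressWarnings(trackPitch(w))),
               "cycles|short|voiced")
})

test_that("jitter metrics match closed forms on constructed sequences", {
  mkCyc <- function(T, A) new("CycleSequence", marks = cumsum(c(0, T)),
                              periods = T, amplitudes = A)
  const <- mkCyc(rep(0.01, 20), rep(1, 20))
  expect_equal(unname(jitterMetrics(const)), rep(0, 5))
  delta <- 0.01
  alt <- mkCyc(0.01 * (1 + delta * rep(c(1, -1), 10)), rep(1, 20))
  jm <- jitterMetrics(alt)
  expect_equal(unname(jm["jitter_local_pct"]), 2 * delta * 100, tolerance = 1e-10)
  expect_equal(unname(jm["jitter_ddp_pct"]), 4 * delta * 100, tolerance = 1e-10)
  expect_equal(unname(jm["jitter_rap_pct"]), 4 * delta * 100 / 3, tolerance = 1e-10)
  # DDP = 3 RAP identically, on random sequences
  set.seed(1)
  for (i in 1:5) {
    r <- mkCyc(0.01 * (1 + stats::rnorm(30, 0, 0.02)), rep(1, 30))
    jr <- jitterMetrics(r)
    expect_equal(unname(jr["jitter_ddp_pct"]), unname(3 * jr["jitter_rap_pct"]),
                 tolerance = 1e-12)
  }
  expect_error(jitterMetrics(mkCyc(rep(0.01, 11), rep(1, 11))), "insufficient")
})

test_that("shimmer metrics match closed forms on constructed sequences", {
  mkCyc <- function(T, A) new("CycleSequence", marks = cumsum(c(0, T)),
                              periods = T, amplitudes = A)
  const <- mkCyc(rep(0.01, 20), rep(0.8, 20))
  expect_equal(unname(shimmerMetrics(const)), rep(0, 6))
  eps <- 0.02
  alt <- mkCyc(rep(0.01, 20), 1 + eps * rep(c(1, -1), 10))
  sm <- shimmerMetrics(alt)
  expect_equal(unname(sm["shimmer_local_pct"]), 2 * eps * 100, tolerance = 1e-10)
  expect_equal(unname(sm["shimmer_local_db"]),
               abs(20 * log10((1 + eps) / (1 - eps))), tolerance = 1e-10)
  set.seed(2)
  for (i in 1:5) {
    r <- mkCyc(rep(0.01, 30), 1 + stats::rnorm(30, 0, 0.05))
    sr <- shimmerMetrics(r)
    expect_equal(unname(sr["shimmer_dda_pct"]),
                 unname(3 * sr["shimmer_apq3_pct"]), tolerance = 1e-12)
  }
  bad <- mkCyc(rep(0.01, 20), c(rep(1, 19), -0.1))
  expect_error(shimmerMetrics(bad), "positive")
})

test_that("HNR behaves correctly in limiting cases", {
  fs <- 8000
  per <- sin(2 * pi * 150 * seq_len(2 * fs) / fs) +
         0.3 * sin(2 * pi * 300 * seq_len(2 * fs) / fs)
  wper <- waveform(per / max(abs(per)), fs)
  expect_gte(harmonicsToNoiseRatio(wper, trackPitch(wper)), 35)
  set.seed(1)
  nz <- stats::rnorm(2 * fs)
  nz <- nz * sqrt(mean(per^2) / mean(nz^2))  # equal-power mixture
  mix <- per + nz
  wmix <- waveform(mix / max(abs(mix)), fs)
  expect_lt(abs(harmonicsToNoiseRatio(wmix, trackPitch(wmix))), 1.5)
})

test_that("formants of a synthetic /a/ are localized correctly", {
  sp <- vowelSpec(duration = 2, f0 = 130, jitter_pct = 0.3, shimmer_pct = 2,
                  hnr_db = 25)
  w <- synthesizeVowel(sp, fs = 44100, seed = 9)
  fm <- formantSummary(w)
  expect_lt(abs(fm["f1_mean_hz"] - 700), 50)
  expect_lt(abs(fm["f2_mean_hz"] - 1220), 80)
  # stationary vowel: formant tracks are stable
  expect_lt(fm["f1_sd_hz"], 0.1 * fm["f1_mean_hz"])
  expect_lt(fm["f2_sd_hz"], 0.1 * fm["f2_mean_hz"])
  sine <- formantSummary(toneWave(200, 8820, dur = 1))
  expect_true(isTRUE(attr(sine, "partial")))
})

test_that("the phonation vector has 23 entries and is gain-invariant", {
  sp <- vowelSpec(duration = 2, f0 = 150, jitter_pct = 1, shimmer_pct = 4,
                  hnr_db = 18)
  w <- synthesizeVowel(sp, fs = 44100, seed = 12)
  pf <- phonationFeatures(w, "S001")
  expect_length(pf, 23L)
  expect_identical(names(pf), phonationFeatureNames())
  expect_identical(attr(pf, "subject_id"), "S001")
  # halving the gain (exact in binary floating point) changes nothing:
  # every feature is relative or spectral
  pf_half <- phonationFeatures(waveform(samples(w) * 0.5, 44100), "S001")
  expect_identical(as.numeric(pf), as.numeric(pf_half))
  # two subjects are keyed apart
  pf2 <- phonationFeatures(w, "S002")
  expect_false(identical(attr(pf, "subject_id"), attr(pf2, "subject_id")))
})

test_that("zero-perturbation vowel yields near-zero perturbation features", {
  sp <- vowelSpec(duration = 2, f0 = 150, jitter_pct = 0, shimmer_pct = 0,
                  tremor_depth = 0, hnr_db = Inf)
  w <- synthesizeVowel(sp, fs = 44100, seed = 13)
  pf <- phonationFeatures(w, "S003")
  expect_lt(pf["jitter_local_pct"], 0.05)
  expect_lt(pf["shimmer_local_pct"], 0.6)
  expect_lt(pf["f0_sd_hz"], 1)
})
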