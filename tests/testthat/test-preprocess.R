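# WAV IO, normalization, decimation, trimming, voiced-segment selection
# and clipping.

test_that("WAV round trip preserves samples to 16-bit accuracy", {
  w <- toneWave(440, 8000, dur = 1, amp = 1)
  path <- tempfile(fileext = ".wav")
  writeWav(w, path)
  r <- readWav(path)
  expect_equal(sampleRate(r), 8000)
  expect_lte(max(abs(samples(r) - samples(w))), 2^-15)
  w44 <- toneWave(440, 44100, dur = 0.2)
  writeWav(w44, path)
  expect_equal(sampleRate(readWav(path)), 44100)
})

test_that("malformed WAV inputs raise format errors", {
  empty <- tempfile(fileext = ".wav")
  file.create(empty)
  expect_error(readWav(empty), "too short")
  expect_error(readWav(tempfile()), "not found")
  # flip the channel-count field of a valid file to stereo
  path <- tempfile(fileext = ".wav")
  writeWav(toneWave(440, 8000, dur = 0.1), path)
  bytes <- readBin(path, "raw", file.size(path))
  bytes[23L] <- as.raw(2L)  # fmt chunk channel count (little endian)
  writeBin(bytes, path)
  expect_error(readWav(path), "mono")
})

test_that("amplitude normalization is scale-invariant and idempotent", {
  w <- toneWave(200, 8000, amp = 0.25)
  n1 <- normalizeAmplitude(w)
  n2 <- normalizeAmplitude(waveform(samples(w) * 0.25, 8000))
  expect_equal(max(abs(samples(n1))), 1)
  expect_equal(samples(n1), samples(n2))
  expect_equal(samples(normalizeAmplitude(n1)), samples(n1))
  expect_error(normalizeAmplitude(waveform(numeric(100), 8000)), "degenerate")
})

test_that("decimation preserves the passband and suppresses aliases", {
  expect_equal(sampleRate(decimateWaveform(toneWave(1000, 44100), 5)), 8820)
  w <- toneWave(300, 8000)
  expect_identical(samples(decimateWaveform(w, 1)), samples(w))
  d1k <- decimateWaveform(toneWave(1000, 44100), 5)
  expect_lt(abs(dbRel(rmsOf(d1k), rmsOf(toneWave(1000, 44100)))), 1)
  d43 <- decimateWaveform(toneWave(4300, 44100), 5)
  expect_lt(dbRel(rmsOf(d43), rmsOf(toneWave(4300, 44100))), -40)
  expect_error(decimateWaveform(w, 2.5), "integer")
})

test_that("silence trimming retains the voiced interval", {
  fs <- 8000
  sil <- numeric(0.5 * fs)
  vow <- samples(toneWave(180, fs, dur = 2, amp = 0.8))
  w <- waveform(c(sil, vow, sil), fs)
  tr <- trimSilence(w)
  expect_lte(abs(duration(tr$waveform) - 2), 0.04)  # within one window + hop
  expect_lt(abs(tr$start_s - 0.5), 0.05)
  # all-voiced input is unchanged
  wv <- waveform(vow, fs)
  expect_equal(duration(trimSilence(wv)$waveform), 2, tolerance = 0.02)
  expect_error(trimSilence(waveform(numeric(fs), fs)), "degenerate")
})

test_that("longest voiced segment survives pauses and rejects noise", {
  fs <- 8000
  v1 <- samples(toneWave(150, fs, dur = 1, amp = 0.8))
  v2 <- samples(toneWave(150, fs, dur = 2, amp = 0.8))
  pause <- numeric(0.5 * fs)
  w <- waveform(c(v1, pause, v2), fs)
  seg <- longestVoicedSegment(w)
  expect_lt(abs(duration(seg) - 2), 0.1)
  # a single continuous vowel comes back whole
  whole <- longestVoicedSegment(waveform(v2, fs))
  expect_gt(duration(whole), 1.9)
  for (s in 1:3) {
    set.seed(s)
    noise <- waveform(stats::rnorm(2 * fs) / 5, fs)
    expect_error(longestVoicedSegment(noise), "voiced")
  }
})

test_that("center clipping returns exact sample counts", {
  w <- waveform(stats::rnorm(26400) / 5, 8000)
  expect_equal(length(samples(centerClip(w))), 12000L)
  w15 <- waveform(stats::rnorm(12000) / 5, 8000)
  expect_identical(samples(centerClip(w15)), samples(w15))
  expect_error(centerClip(waveform(stats::rnorm(11200) / 5, 8000)),
               "too-short")
})

test_that("the preprocessing chain is idempotent on its own output", {
  sp <- vowelSpec(duration = 2.5, f0 = 140, jitter_pct = 0.5, shimmer_pct = 3,
                  hnr_db = 20)
  w <- synthesizeVowel(sp, fs = 44100, seed = 11)
  w <- applyChannel(w, channelSpec("smartphone"))
  p1 <- preprocessWaveform(w)
  p2 <- preprocessWaveform(p1)
  expect_equal(sampleRate(p1), 8820)
  expect_lt(abs(duration(p1) - duration(p2)), 0.1)
  expect_lte(max(abs(samples(p1))), 1)
})
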