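# Synthetic vowel generator: parameter recovery, channel model, cohort
# determinism.

test_that("zero-perturbation spec yields a perfectly periodic vowel", {
  sp <- vowelSpec(duration = 2, f0 = 150, jitter_pct = 0, shimmer_pct = 0,
                  tremor_depth = 0, hnr_db = Inf)
  w <- synthesizeVowel(sp, fs = 44100, seed = 1)
  expect_lte(max(abs(samples(w))), 1)
  pt <- trackPitch(w)
  f0v <- pt@f0[pt@f0 > 0]
  expect_lt(abs(mean(f0v) - 150) / 150, 0.01)
  cyc <- extractCycles(w, pt)
  expect_lt(jitterMetrics(cyc)["jitter_local_pct"], 0.05)
  expect_lt(shimmerMetrics(cyc)["shimmer_local_pct"], 0.6)
})

test_that("target HNR is recovered by the estimator", {
  sp <- vowelSpec(duration = 3, f0 = 150, jitter_pct = 0.3, shimmer_pct = 2,
                  hnr_db = 20)
  w <- synthesizeVowel(sp, fs = 44100, seed = 4)
  hnr <- harmonicsToNoiseRatio(w, trackPitch(w))
  expect_gte(hnr, 18)
  expect_lte(hnr, 22)
})

test_that("invalid vowel specs are rejected", {
  expect_error(vowelSpec(duration = 1.0), "duration")
  expect_error(vowelSpec(f0 = 50), "f0")
  bad_formants <- matrix(c(700, 130, 1220, -10), ncol = 2, byrow = TRUE)
  expect_error(vowelSpec(formants = bad_formants), "bandwidth")
  expect_error(synthesizeVowel(vowelSpec(), fs = 11025), "8000 or 44100")
})

test_that("injected jitter is recovered monotonically across a grid", {
  grid <- c(0.25, 0.5, 1, 2, 4)
  measured <- vapply(seq_along(grid), function(i) {
    sp <- vowelSpec(duration = 2.5, f0 = 150, jitter_pct = grid[i],
                    shimmer_pct = 0, hnr_db = Inf)
    w <- synthesizeVowel(sp, fs = 44100, seed = 100 + i)
    jitterMetrics(extractCycles(w, trackPitch(w)))["jitter_local_pct"]
  }, numeric(1))
  expect_gt(cor(grid, measured, method = "spearman"), 0.9)
  expect_lt(abs(measured[4L] - 2), 0.5)
})

test_that("telephone channel band-limits and resamples to 8 kHz", {
  ch <- channelSpec("telephone")
  out1k <- applyChannel(toneWave(1000, 44100), ch)
  expect_equal(sampleRate(out1k), 8000)
  expect_lt(abs(dbRel(rmsOf(out1k), rmsOf(toneWave(1000, 44100)))), 3)
  out5k <- applyChannel(toneWave(5000, 44100), ch)
  expect_lt(dbRel(rmsOf(out5k), rmsOf(out1k)), -40)
  # stopband on both sides of the passband, relative to 1 kHz
  out100 <- applyChannel(toneWave(100, 44100), ch)
  out4k <- applyChannel(toneWave(3950, 44100), ch)
  expect_lt(dbRel(rmsOf(out100), rmsOf(out1k)), -40)
  expect_lt(dbRel(rmsOf(out4k), rmsOf(out1k)), -40)
})

test_that("smartphone channel is an identity filter with quantization", {
  ch <- channelSpec("smartphone")
  w <- toneWave(440, 44100)
  out <- applyChannel(w, ch)
  expect_equal(sampleRate(out), 44100)
  expect_lte(max(abs(samples(out))), 1)
  expect_lt(max(abs(samples(out) - samples(w))), 2^-15)
  expect_error(waveform(numeric(0), 8000))
})

test_that("cohort generation is deterministic and correctly labeled", {
  cs <- cohortSpec(n_pd = 2, n_hc = 2, seed = 7)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  c1 <- generateCohort(cs, d1)
  c2 <- generateCohort(cs, d2)
  expect_equal(nrow(c1$manifest), 4L)
  expect_equal(sum(c1$manifest$label == "PD"), 2L)
  expect_false(anyDuplicated(c1$manifest$subject_id) > 0)
  for (i in seq_len(4L)) {
    b1 <- readBin(c1$manifest$path[i], "raw", file.size(c1$manifest$path[i]))
    b2 <- readBin(c2$manifest$path[i], "raw", file.size(c2$manifest$path[i]))
    expect_identical(b1, b2)
  }
  expect_identical(c1$manifest$label, c2$manifest$label)
  expect_error(cohortSpec(n_pd = 0, n_hc = 2), "n_pd")
})

test_that("PD group draws measurably higher jitter than HC", {
  # small groups suffice: the default parameter ranges are well separated
  cs <- cohortSpec(n_pd = 6, n_hc = 6, seed = 3)
  coh <- generateCohort(cs, file.path(tempdir(), "coh_sep"))
  jit <- vapply(seq_len(12L), function(i) {
    w <- preprocessWaveform(readWav(coh$manifest$path[i]))
    jitterMetrics(extractCycles(w, trackPitch(w)))["jitter_local_pct"]
  }, numeric(1))
  pd <- jit[coh$manifest$label == "PD"]
  hc <- jit[coh$manifest$label == "HC"]
  expect_lt(stats::wilcox.test(pd, hc, alternative = "greater")$p.value, 0.01)
})
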