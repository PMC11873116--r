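# Synthetic sustained-vowel generator. Source-filter model: a band-limited
# glottal pulse train with -12 dB/octave spectral tilt, per-cycle period
# and amplitude perturbations (jitter, shimmer), slow F0 tremor and
# transient distortion events, filtered through cascaded second-order
# formant resonators, plus aspiration noise at a target harmonics-to-noise
# ratio. The generator's job is to realize parameters the downstream
# estimators can recover, so every perturbation is injected on the scale
# its estimator measures.

# Calibration of the i.i.d. Gaussian perturbation: if eta_i ~ N(0, sigma)
# then E|eta_i - eta_{i-1}| = 2 * sigma / sqrt(pi), so the "local"
# jitter/shimmer estimator recovers the nominal percentage in expectation
# when sigma = (pct / 100) * sqrt(pi) / 2. Frozen analytic constant.
PERTURB_CALIB <- sqrt(pi) / 2

#' Construct a VowelSpec
#'
#' @param duration phonation length, seconds (>= 1.5).
#' @param f0 mean fundamental frequency, Hz.
#' @param jitter_pct expected local jitter, percent (cycle-to-cycle period
#'   perturbation).
#' @param shimmer_pct expected local shimmer, percent (cycle-to-cycle
#'   amplitude perturbation).
#' @param tremor_rate slow F0 modulation rate, Hz.
#' @param tremor_depth fractional F0 excursion of the tremor (0--0.1).
#' @param hnr_db target harmonics-to-noise ratio in dB; `Inf` disables the
#'   aspiration noise.
#' @param formants two-column matrix of /a/ formant (center, bandwidth)
#'   pairs in Hz; defaults to (700,130), (1220,70), (2600,160), (3500,200).
#' @param distortion_rate transient distortion events per second.
#' @param distortion_duration event duration, seconds.
#' @return A validated [VowelSpec-class].
#' @examples
#' spec <- vowelSpec(duration = 2, f0 = 150, jitter_pct = 1, shimmer_pct = 4)
#' w <- synthesizeVowel(spec, fs = 44100, seed = 1)
#' @export
vowelSpec <- function(duration = 3, f0 = 130, jitter_pct = 0.5,
                      shimmer_pct = 3, tremor_rate = 5, tremor_depth = 0,
                      hnr_db = 20,
                      formants = defaultFormants(),
                      distortion_rate = 0, distortion_duration = 0.1) {
  new("VowelSpec", duration = duration, f0 = f0, jitter_pct = jitter_pct,
      shimmer_pct = shimmer_pct, tremor_rate = tremor_rate,
      tremor_depth = tremor_depth, hnr_db = hnr_db,
      formants = formants, distortion_rate = distortion_rate,
      distortion_duration = distortion_duration)
}

#' Default /a/ formant table
#'
#' Centers and bandwidths (Hz) of the first four formants of the open
#' vowel /a/: F1 near 700 Hz and F2 near 1220 Hz — the band where
#' PD-vs-control spectrogram differences concentrate.
#' @return 4 x 2 matrix (center, bandwidth).
#' @export
defaultFormants <- function() {
  matrix(c(700, 130, 1220, 70, 2600, 160, 3500, 200),
         ncol = 2, byrow = TRUE,
         dimnames = list(paste0("f", 1:4), c("center", "bandwidth")))
}

#' Construct a ChannelSpec
#'
#' @param kind `"telephone"` (0.3--3.4 kHz band-limited, 8 kHz output) or
#'   `"smartphone"` (full band, 44.1 kHz).
#' @param passband length-2 numeric, telephone passband in Hz.
#' @return A validated [ChannelSpec-class].
#' @export
channelSpec <- function(kind = c("smartphone", "telephone"),
                        passband = c(300, 3400)) {
  kind <- match.arg(kind)
  if (kind == "smartphone") passband <- c(0, 22050)
  new("ChannelSpec", kind = kind, passband = passband,
      target_fs = if (kind == "telephone") 8000 else 44100, bit_depth = 16)
}

# Second-order resonator at (f, bw) Hz applied recursively; gain-normalized
# at the resonance frequency.
applyResonator <- function(x, f, bw, fs) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * f / fs
  b0 <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
  y <- stats::filter(b0 * x, filter = c(2 * r * cos(theta), -r^2),
                     method = "recursive")
  as.numeric(y)
}

#' Synthesize one sustained vowel
#'
#' Construction contract: glottal cycle lengths are
#' `T_i = (1 / f0_i) * (1 + eta_i)` with `eta_i ~ N(0, sigma_j)` scaled so
#' the local jitter estimator recovers `jitter_pct` in expectation;
#' `f0_i` is modulated by `tremor_depth * sin(2 * pi * tremor_rate * t)`
#' and by transient distortion events; per-cycle amplitudes are
#' `1 + xi_i` with the analogous shimmer scaling; the pulse train carries a
#' -12 dB/octave spectral tilt and is filtered by cascaded second-order
#' resonators at the formants; aspiration noise is added with power set so
#' the periodic-to-noise power ratio equals `hnr_db`.
#'
#' @param spec a [VowelSpec-class].
#' @param fs sampling rate, 8000 or 44100 Hz.
#' @param seed integer seed (NULL uses the current RNG state).
#' @return A [Waveform-class] with peak amplitude 0.9.
#' @export
synthesizeVowel <- function(spec, fs = 44100, seed = NULL) {
  stopifnot(is(spec, "VowelSpec"))
  validObject(spec)
  if (!fs %in% c(8000, 44100)) stop("'fs' must be 8000 or 44100 Hz")
  withSeed(seed, {
    dur <- spec@duration
    sigma_j <- spec@jitter_pct / 100 * PERTURB_CALIB
    sigma_s <- spec@shimmer_pct / 100 * PERTURB_CALIB

    # distortion events: piecewise F0/amplitude deviations at random times
    n_events <- stats::rpois(1, spec@distortion_rate * dur)
    ev_start <- sort(stats::runif(n_events, 0, dur))
    ev_f0dev <- stats::runif(n_events, -0.08, 0.08)
    ev_ampdev <- stats::runif(n_events, 0.3, 0.7)

    distortionAt <- function(t) {
      f0_fac <- 1; amp_fac <- 1
      if (n_events > 0) {
        act <- which(t >= ev_start & t < ev_start + spec@distortion_duration)
        if (length(act)) {
          f0_fac <- 1 + sum(ev_f0dev[act])
          amp_fac <- prod(ev_ampdev[act])
        }
      }
      c(f0_fac, amp_fac)
    }

    # cycle-by-cycle construction of glottal pulse instants
    t <- 0; marks <- numeric(0); amps <- numeric(0)
    while (t < dur) {
      d <- distortionAt(t)
      f0_i <- spec@f0 *
        (1 + spec@tremor_depth * sin(2 * pi * spec@tremor_rate * t)) * d[1L]
      T_i <- (1 / f0_i) * (1 + stats::rnorm(1, 0, sigma_j))
      T_i <- max(T_i, 0.2 / spec@f0)
      marks <- c(marks, t)
      amps <- c(amps, max(1 + stats::rnorm(1, 0, sigma_s), 0.05) * d[2L])
      t <- t + T_i
    }

    n <- as.integer(round(dur * fs))
    pulses <- numeric(n)
    idx <- marks * fs
    i0 <- floor(idx) + 1L
    frac <- idx - (i0 - 1L)
    ok <- i0 >= 1L & i0 < n
    # linear-interpolated (fractional-delay) impulse placement preserves
    # sub-sample timing of the perturbed cycles
    pulses[i0[ok]] <- pulses[i0[ok]] + amps[ok] * (1 - frac[ok])
    pulses[i0[ok] + 1L] <- pulses[i0[ok] + 1L] + amps[ok] * frac[ok]

    # -12 dB/octave glottal tilt: two cascaded leaky integrators
    a <- exp(-2 * pi * 100 / fs)
    src <- as.numeric(stats::filter(pulses, a, method = "recursive"))
    src <- as.numeric(stats::filter(src, a, method = "recursive"))
    src <- src - mean(src)

    voiced <- src
    for (i in seq_len(nrow(spec@formants)))
      voiced <- applyResonator(voiced, spec@formants[i, 1L],
                               spec@formants[i, 2L], fs)

    if (is.finite(spec@hnr_db)) {
      noise <- stats::rnorm(n)
      for (i in seq_len(nrow(spec@formants)))
        noise <- applyResonator(noise, spec@formants[i, 1L],
                                spec@formants[i, 2L], fs)
      p_sig <- mean(voiced^2)
      p_noise <- mean(noise^2)
      noise <- noise * sqrt(p_sig / (p_noise * 10^(spec@hnr_db / 10)))
      voiced <- voiced + noise
    }

    # gentle onset/offset ramps (50 ms) emulate phonation start/stop
    ramp <- as.integer(round(0.05 * fs))
    if (2L * ramp < n) {
      env <- c(seq(0, 1, length.out = ramp), rep(1, n - 2L * ramp),
               seq(1, 0, length.out = ramp))
      voiced <- voiced * env
    }
    voiced <- voiced / max(abs(voiced)) * 0.9
    waveform(voiced, fs, provenance = "synth")
  })
}

#' Pass a waveform through a recording-channel model
#'
#' Telephone: zero-phase band-pass FIR to the passband (> 60 dB stopband),
#' Fourier resampling to 8 kHz. Smartphone: identity filter at 44.1 kHz.
#' Both paths quantize to 16-bit (round to nearest, no dither) and rescale
#' to `[-1, 1]`.
#'
#' @param w a [Waveform-class].
#' @param ch a [ChannelSpec-class].
#' @return Channel-filtered [Waveform-class] at `ch@target_fs`.
#' @export
applyChannel <- function(w, ch) {
  stopifnot(is(w, "Waveform"), is(ch, "ChannelSpec"))
  validObject(ch)
  if (length(w@samples) == 0L) stop("empty waveform")
  x <- w@samples
  fs <- w@fs
  if (ch@kind == "telephone") {
    # transition width 150 Hz: 100 Hz and 4 kHz sit in the (~74 dB) stopband
    n_taps <- as.integer(ceiling(5.5 * fs / 150))
    h <- firBandpass(ch@passband[1L], ch@passband[2L], fs, n_taps)
    x <- filterFIR(x, h)
    if (fs != ch@target_fs) x <- resampleFFT(x, fs, ch@target_fs)
    fs <- ch@target_fs
  } else if (fs != ch@target_fs) {
    stop("smartphone channel expects input already at 44100 Hz")
  }
  x <- pmin(pmax(x, -1), 1)
  x <- pmin(pmax(round(x * 32768), -32768), 32767) / 32768
  waveform(x, fs, provenance = paste0(w@provenance, "|", ch@kind))
}

# Default per-group parameter ranges: the stated world of the cohort.
# Healthy sustained phonation sits at low jitter/shimmer and high HNR;
# the PD-like group has elevated perturbations, reduced HNR, audible slow
# tremor ("ripples") and occasional transient distortions.
defaultGroupRanges <- function(group = c("hc", "pd")) {
  group <- match.arg(group)
  if (group == "hc")
    list(duration = c(2.5, 6), jitter_pct = c(0.3, 0.7),
         shimmer_pct = c(2, 5), tremor_rate = c(4, 7),
         tremor_depth = c(0, 0.004), hnr_db = c(18, 25),
         distortion_rate = c(0, 0), distortion_duration = c(0.1, 0.1))
  else
    list(duration = c(2.5, 6), jitter_pct = c(1.5, 4),
         shimmer_pct = c(6, 12), tremor_rate = c(4, 7),
         tremor_depth = c(0.01, 0.04), hnr_db = c(8, 15),
         distortion_rate = c(0.2, 1), distortion_duration = c(0.05, 0.15))
}

#' Construct a CohortSpec
#'
#' Defaults encode the emulated study populations: group mean F0 follows
#' the printed smartphone-cohort estimates (116 Hz healthy males, 123 Hz
#' PD males, 192 Hz healthy females, 188 Hz PD females, inter-speaker SD
#' 10 Hz), and the PD group draws elevated jitter/shimmer, reduced HNR,
#' slow F0 tremor and transient distortions (see [vowelSpec()]).
#'
#' @param n_pd,n_hc group sizes (>= 1).
#' @param channel a [ChannelSpec-class] (default smartphone).
#' @param seed integer seed controlling the entire cohort draw.
#' @param pd_ranges,hc_ranges named lists of length-2 ranges overriding the
#'   defaults per parameter.
#' @param sex_mix proportion of males (default 0.5).
#' @return A validated [CohortSpec-class].
#' @export
cohortSpec <- function(n_pd = 30, n_hc = 30, channel = channelSpec("smartphone"),
                       seed = 1, pd_ranges = list(), hc_ranges = list(),
                       sex_mix = 0.5) {
  pd <- utils::modifyList(defaultGroupRanges("pd"), pd_ranges)
  hc <- utils::modifyList(defaultGroupRanges("hc"), hc_ranges)
  new("CohortSpec", n_pd = n_pd, n_hc = n_hc, pd_ranges = pd, hc_ranges = hc,
      sex_mix = sex_mix,
      f0_by_sex = c(hc_male = 116, pd_male = 123, hc_female = 192,
                    pd_female = 188),
      channel = channel, seed = seed)
}

#' Generate a labeled synthetic cohort of sustained-vowel recordings
#'
#' Draws one [VowelSpec-class] per subject from the group parameter
#' ranges, synthesizes the vowel at 44.1 kHz, passes it through the
#' channel model and writes one PCM16 WAV per subject plus a manifest CSV
#' (`subject_id,label,sex,path,channel`). Deterministic given
#' `cs@seed`: two runs produce bit-identical WAV files and manifest.
#'
#' @param cs a [CohortSpec-class].
#' @param dir output directory (created if missing).
#' @return A list with `manifest` (data.frame) and `specs` (named list of
#'   the per-subject [VowelSpec-class] ground truth).
#' @export
generateCohort <- function(cs, dir) {
  stopifnot(is(cs, "CohortSpec"))
  validObject(cs)
  if (cs@n_pd < 1 || cs@n_hc < 1) stop("group counts must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- cs@n_pd + cs@n_hc
  labels <- c(rep("PD", cs@n_pd), rep("HC", cs@n_hc))
  rows <- vector("list", n)
  specs <- vector("list", n)
  withSeed(as.integer(cs@seed), {
    sexes <- ifelse(stats::runif(n) < cs@sex_mix, "M", "F")
    for (i in seq_len(n)) {
      grp <- if (labels[i] == "PD") "pd" else "hc"
      rng <- if (grp == "pd") cs@pd_ranges else cs@hc_ranges
      draw <- function(nm) stats::runif(1, rng[[nm]][1L], rng[[nm]][2L])
      f0_mu <- cs@f0_by_sex[[paste0(grp, "_", if (sexes[i] == "M") "male" else "female")]]
      f0 <- max(60, min(400, stats::rnorm(1, f0_mu, 10)))
      sp <- vowelSpec(duration = draw("duration"), f0 = f0,
                      jitter_pct = draw("jitter_pct"),
                      shimmer_pct = draw("shimmer_pct"),
                      tremor_rate = draw("tremor_rate"),
                      tremor_depth = draw("tremor_depth"),
                      hnr_db = draw("hnr_db"),
                      distortion_rate = draw("distortion_rate"),
                      distortion_duration = draw("distortion_duration"))
      sid <- sprintf("S%03d", i)
      w <- synthesizeVowel(sp, fs = 44100,
                           seed = stageSeed(cs@seed, paste0("subject", i)))
      # leading/trailing silence so the trimming stage has real work to do
      pad0 <- numeric(as.integer(round(stats::runif(1, 0.1, 0.4) * 44100)))
      pad1 <- numeric(as.integer(round(stats::runif(1, 0.1, 0.4) * 44100)))
      w <- waveform(c(pad0, w@samples, pad1), 44100, provenance = "synth")
      w <- applyChannel(w, cs@channel)
      path <- file.path(dir, paste0(sid, ".wav"))
      writeWav(w, path)
      specs[[i]] <- sp
      names(specs)[i] <- sid
      rows[[i]] <- data.frame(subject_id = sid, label = labels[i],
                              sex = sexes[i], path = path,
                              channel = cs@channel@kind,
                              stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, specs = specs)
}
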