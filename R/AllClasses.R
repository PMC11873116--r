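#' @import methods
NULL

#' Waveform: mono audio samples with sampling rate
#'
#' The central audio container of the package: a mono sample sequence in
#' `[-1, 1]` together with its sampling rate in Hz and a free-text
#' provenance tag that downstream stages extend (e.g. `"synth"`,
#' `"synth|trim"`).
#'
#' @slot samples numeric vector of samples, `max(abs(samples)) <= 1`.
#' @slot fs sampling rate in Hz (positive scalar).
#' @slot provenance free-text processing history.
#'
#' @seealso [waveform()], [samples()], [sampleRate()], [duration()]
#' @export
setClass("Waveform",
  representation(samples = "numeric", fs = "numeric", provenance = "character"),
  prototype(provenance = "")
)

setValidity("Waveform", function(object) {
  msg <- NULL
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "'samples' must contain at least one sample")
  else if (anyNA(object@samples) || !all(is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  else if (max(abs(object@samples)) > 1 + 1e-9)
    msg <- c(msg, "'samples' must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Waveform
#'
#' @param samples numeric samples in `[-1, 1]`.
#' @param fs sampling rate (Hz).
#' @param provenance free-text origin tag.
#' @return A [Waveform-class] object.
#' @examples
#' w <- waveform(sin(2 * pi * 220 * seq(0, 1, by = 1 / 8000)), fs = 8000)
#' duration(w)
#' @export
waveform <- function(samples, fs, provenance = "") {
  new("Waveform", samples = as.numeric(samples), fs = as.numeric(fs),
      provenance = provenance)
}

#' VowelSpec: parameters of one synthetic sustained vowel
#'
#' Describes the "ground truth" of a synthetic /a/ phonation: fundamental
#' frequency, cycle-to-cycle perturbations (jitter, shimmer), slow pitch
#' tremor, target harmonics-to-noise ratio, vocal-tract formants and
#' transient distortion events.
#'
#' @slot duration seconds (>= 1.5).
#' @slot f0 mean fundamental frequency, Hz (60--400).
#' @slot jitter_pct expected cycle-to-cycle period perturbation, percent.
#' @slot shimmer_pct expected cycle-to-cycle amplitude perturbation, percent.
#' @slot tremor_rate slow F0 modulation rate, Hz.
#' @slot tremor_depth fractional F0 excursion of the tremor (0--0.1).
#' @slot hnr_db target harmonics-to-noise ratio, dB (`Inf` = no noise).
#' @slot formants two-column matrix (center Hz, bandwidth Hz), centers
#'   strictly increasing.
#' @slot distortion_rate transient distortion events per second.
#' @slot distortion_duration duration of each distortion event, seconds.
#' @export
setClass("VowelSpec",
  representation(duration = "numeric", f0 = "numeric", jitter_pct = "numeric",
    shimmer_pct = "numeric", tremor_rate = "numeric", tremor_depth = "numeric",
    hnr_db = "numeric", formants = "matrix", distortion_rate = "numeric",
    distortion_duration = "numeric")
)

setValidity("VowelSpec", function(object) {
  msg <- NULL
  if (object@duration < 1.5) msg <- c(msg, "'duration' must be >= 1.5 s")
  if (object@f0 < 60 || object@f0 > 400) msg <- c(msg, "'f0' must lie in [60, 400] Hz")
  if (object@jitter_pct < 0) msg <- c(msg, "'jitter_pct' must be >= 0")
  if (object@shimmer_pct < 0) msg <- c(msg, "'shimmer_pct' must be >= 0")
  if (object@tremor_depth < 0 || object@tremor_depth > 0.1)
    msg <- c(msg, "'tremor_depth' must lie in [0, 0.1]")
  if (ncol(object@formants) != 2L) msg <- c(msg, "'formants' needs 2 columns (center, bandwidth)")
  else {
    if (any(diff(object@formants[, 1L]) <= 0))
      msg <- c(msg, "formant centers must be strictly increasing")
    if (any(object@formants[, 2L] <= 0))
      msg <- c(msg, "formant bandwidths must be positive (unstable resonator otherwise)")
  }
  if (object@distortion_rate < 0) msg <- c(msg, "'distortion_rate' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' ChannelSpec: recording-channel model
#'
#' Two channel conditions are modelled: an analog telephone line
#' (band-limited to roughly 0.3--3.4 kHz, 8 kHz sampling) and a smartphone
#' recording (full band at 44.1 kHz). Both quantize to 16-bit PCM.
#'
#' @slot kind `"telephone"` or `"smartphone"`.
#' @slot passband numeric length-2, (low, high) Hz.
#' @slot target_fs output sampling rate, Hz.
#' @slot bit_depth bits per sample (16).
#' @export
setClass("ChannelSpec",
  representation(kind = "character", passband = "numeric",
    target_fs = "numeric", bit_depth = "numeric")
)

setValidity("ChannelSpec", function(object) {
  msg <- NULL
  if (!object@kind %in% c("telephone", "smartphone"))
    msg <- c(msg, "'kind' must be 'telephone' or 'smartphone'")
  if (object@bit_depth != 16) msg <- c(msg, "'bit_depth' must be 16")
  if (identical(object@kind, "telephone")) {
    if (object@target_fs != 8000) msg <- c(msg, "telephone channel requires target_fs = 8000")
    if (object@passband[1L] < 300 || object@passband[2L] > 3400)
      msg <- c(msg, "telephone passband must lie within (300, 3400) Hz")
  }
  if (identical(object@kind, "smartphone") && object@target_fs != 44100)
    msg <- c(msg, "smartphone channel requires target_fs = 44100")
  if (is.null(msg)) TRUE else msg
})

#' CohortSpec: sampling plan for a synthetic PD/HC cohort
#'
#' Group-level parameter ranges from which per-subject [VowelSpec-class]
#' objects are drawn, one recording per subject.
#'
#' @slot n_pd,n_hc subject counts per group (>= 1).
#' @slot pd_ranges,hc_ranges named lists of length-2 numeric ranges, one per
#'   VowelSpec parameter (see [cohortSpec()] for the defaults).
#' @slot sex_mix proportion of male subjects (0--1).
#' @slot f0_by_sex named numeric: mean F0 (Hz) for `hc_male`, `pd_male`,
#'   `hc_female`, `pd_female`.
#' @slot channel a [ChannelSpec-class].
#' @slot seed integer RNG seed for the cohort draw.
#' @export
setClass("CohortSpec",
  representation(n_pd = "numeric", n_hc = "numeric", pd_ranges = "list",
    hc_ranges = "list", sex_mix = "numeric", f0_by_sex = "numeric",
    channel = "ChannelSpec", seed = "numeric")
)

setValidity("CohortSpec", function(object) {
  msg <- NULL
  if (object@n_pd < 1 || object@n_hc < 1) msg <- c(msg, "'n_pd' and 'n_hc' must be >= 1")
  if (object@sex_mix < 0 || object@sex_mix > 1) msg <- c(msg, "'sex_mix' must be in [0, 1]")
  need <- c("hc_male", "pd_male", "hc_female", "pd_female")
  if (!all(need %in% names(object@f0_by_sex)))
    msg <- c(msg, "'f0_by_sex' must name hc_male, pd_male, hc_female, pd_female")
  if (is.null(msg)) TRUE else msg
})

#' PitchTrack: frame-wise fundamental frequency estimates
#'
#' @slot times frame centers, seconds (strictly increasing).
#' @slot f0 per-frame F0 in Hz, 0 for unvoiced frames.
#' @slot strength per-frame voicing strength (peak normalized
#'   autocorrelation, 0--1).
#' @export
setClass("PitchTrack",
  representation(times = "numeric", f0 = "numeric", strength = "numeric")
)

setValidity("PitchTrack", function(object) {
  msg <- NULL
  n <- length(object@times)
  if (length(object@f0) != n || length(object@strength) != n)
    msg <- c(msg, "'times', 'f0' and 'strength' must have equal length")
  if (n > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (any(object@f0 < 0)) msg <- c(msg, "'f0' must be >= 0 (0 = unvoiced)")
  if (is.null(msg)) TRUE else msg
})

#' CycleSequence: glottal cycle marks, periods and peak amplitudes
#'
#' Substrate for the jitter and shimmer metrics: cycle boundary times
#' `t_0..t_N`, per-cycle periods `T_i = t_i - t_(i-1)` and per-cycle peak
#' amplitudes `A_i`.
#'
#' @slot marks cycle boundary times, seconds (N + 1 values).
#' @slot periods per-cycle periods, seconds (N values, positive).
#' @slot amplitudes per-cycle peak amplitudes (N values, positive).
#' @export
setClass("CycleSequence",
  representation(marks = "numeric", periods = "numeric", amplitudes = "numeric")
)

setValidity("CycleSequence", function(object) {
  msg <- NULL
  if (length(object@marks) != length(object@periods) + 1L)
    msg <- c(msg, "'marks' must have one more element than 'periods'")
  if (length(object@periods) != length(object@amplitudes))
    msg <- c(msg, "'periods' and 'amplitudes' must have equal length")
  if (any(object@periods <= 0)) msg <- c(msg, "'periods' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' SpectralSummary: per-recording mean/variance of coefficient tracks
#'
#' @slot kind one of `"lpc"`, `"lar"`, `"lpcc"`, `"mfcc"`.
#' @slot mean_vec,var_vec length-p mean and sample-variance of each
#'   coefficient across analysis frames.
#' @slot subject_id subject identifier.
#' @export
setClass("SpectralSummary",
  representation(kind = "character", mean_vec = "numeric", var_vec = "numeric",
    subject_id = "character")
)

setValidity("SpectralSummary", function(object) {
  msg <- NULL
  if (length(object@mean_vec) != length(object@var_vec))
    msg <- c(msg, "'mean_vec' and 'var_vec' must have equal length")
  if (any(object@var_vec < -1e-12)) msg <- c(msg, "'var_vec' must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' SpectrogramMatrix: time-by-frequency log-energy grid
#'
#' Values are max-normalized log energies (dB for the linear scale,
#' normalized log-mel for the mel scale) so that `max(values) == 0`.
#'
#' @slot values time x frequency matrix, max exactly 0.
#' @slot times frame centers, seconds.
#' @slot freqs bin centers (Hz for linear scale, mel for mel scale).
#' @slot scale `"linear"` or `"mel"`.
#' @slot fs source sampling rate, Hz.
#' @export
setClass("SpectrogramMatrix",
  representation(values = "matrix", times = "numeric", freqs = "numeric",
    scale = "character", fs = "numeric")
)

setValidity("SpectrogramMatrix", function(object) {
  msg <- NULL
  if (!object@scale %in% c("linear", "mel")) msg <- c(msg, "'scale' must be 'linear' or 'mel'")
  if (nrow(object@values) != length(object@times))
    msg <- c(msg, "rows of 'values' must match 'times'")
  if (ncol(object@values) != length(object@freqs))
    msg <- c(msg, "columns of 'values' must match 'freqs'")
  if (length(object@values) && abs(max(object@values)) > 1e-9)
    msg <- c(msg, "'values' must be max-normalized (max == 0)")
  if (is.null(msg)) TRUE else msg
})

#' SpectrogramImage: rendered 600x600 24-bit spectrogram
#'
#' @slot pixels height x width x 3 array in `[0, 1]`.
#' @slot colormap colormap identifier used for rendering.
#' @slot subject_id source subject.
#' @slot scale `"linear"` or `"mel"`.
#' @export
setClass("SpectrogramImage",
  representation(pixels = "array", colormap = "character",
    subject_id = "character", scale = "character")
)

setValidity("SpectrogramImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3L] != 3L)
    return("'pixels' must be a height x width x 3 array")
  if (min(object@pixels) < 0 || max(object@pixels) > 1)
    return("'pixels' must lie in [0, 1]")
  TRUE
})

#' EvalResult: repeated-holdout evaluation result
#'
#' @slot auc per-iteration held-out AUC values.
#' @slot seeds per-iteration split seeds.
#' @slot model classifier kind used.
#' @slot n_train,n_test split sizes of the final iteration.
#' @export
setClass("EvalResult",
  representation(auc = "numeric", seeds = "numeric", model = "character",
    n_train = "numeric", n_test = "numeric")
)

setValidity("EvalResult", function(object) {
  msg <- NULL
  if (any(object@auc < 0 | object@auc > 1)) msg <- c(msg, "'auc' must lie in [0, 1]")
  if (length(object@seeds) != length(object@auc))
    msg <- c(msg, "'seeds' must match 'auc' in length")
  if (is.null(msg)) TRUE else msg
})
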