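# Assembly of the 23-entry phonation feature vector.

#' Names and order of the 23 phonation features
#'
#' Fixed documented ordering: F0 mean/SD (2), formant f1--f4 mean/SD (8),
#' HNR (1), five jitter variants, six shimmer variants, and the fraction
#' of unvoiced frames (the 23rd entry — a standard voice-report quantity
#' completing the enumerable 22).
#'
#' @return Character vector of length 23.
#' @export
phonationFeatureNames <- function() {
  c("f0_mean_hz", "f0_sd_hz",
    "f1_mean_hz", "f1_sd_hz", "f2_mean_hz", "f2_sd_hz",
    "f3_mean_hz", "f3_sd_hz", "f4_mean_hz", "f4_sd_hz",
    "hnr_db",
    "jitter_local_pct", "jitter_local_abs_s", "jitter_rap_pct",
    "jitter_ppq5_pct", "jitter_ddp_pct",
    "shimmer_local_pct", "shimmer_local_db", "shimmer_apq3_pct",
    "shimmer_apq5_pct", "shimmer_apq11_pct", "shimmer_dda_pct",
    "unvoiced_fraction")
}

#' Compute the 23-entry phonation feature vector of one recording
#'
#' Runs pitch tracking, cycle extraction, jitter/shimmer, HNR and formant
#' analysis on a preprocessed voiced segment and assembles the results in
#' the fixed order of [phonationFeatureNames()]. All features are relative
#' or frequency-domain quantities, so the vector is exactly invariant to a
#' global gain applied to the waveform.
#'
#' Exactly one vector is produced per subject. When a sub-metric fails
#' (e.g. too few cycles), its entries are `NA` and the vector carries
#' attribute `incomplete = TRUE` so callers can flag the recording for
#' exclusion.
#'
#' @param w a preprocessed [Waveform-class] (voiced segment).
#' @param subject_id subject identifier stored in the `subject_id`
#'   attribute.
#' @return Named numeric of length 23.
#' @examples
#' w <- synthesizeVowel(vowelSpec(duration = 2, f0 = 150), fs = 44100, seed = 7)
#' pf <- phonationFeatures(w, "S001")
#' round(pf[c("f0_mean_hz", "hnr_db", "jitter_local_pct")], 2)
#' @export
phonationFeatures <- function(w, subject_id = "subject") {
  stopifnot(is(w, "Waveform"))
  out <- stats::setNames(rep(NA_real_, 23L), phonationFeatureNames())
  incomplete <- FALSE
  pt <- trackPitch(w)
  voiced <- pt@f0 > 0
  if (any(voiced)) {
    out["f0_mean_hz"] <- mean(pt@f0[voiced])
    out["f0_sd_hz"] <- if (sum(voiced) > 1L) stats::sd(pt@f0[voiced]) else 0
  } else incomplete <- TRUE
  out["unvoiced_fraction"] <- mean(!voiced)
  cyc <- tryCatch(extractCycles(w, pt), error = function(e) NULL)
  if (!is.null(cyc)) {
    out[names(jitterMetrics(cyc))] <- jitterMetrics(cyc)
    out[names(shimmerMetrics(cyc))] <- shimmerMetrics(cyc)
  } else incomplete <- TRUE
  hnr <- tryCatch(harmonicsToNoiseRatio(w, pt), error = function(e) NA_real_)
  if (is.na(hnr)) incomplete <- TRUE
  out["hnr_db"] <- hnr
  fm <- tryCatch(formantSummary(w), error = function(e) NULL)
  if (!is.null(fm)) {
    out[names(fm)] <- fm
    if (isTRUE(attr(fm, "partial"))) incomplete <- TRUE
  } else incomplete <- TRUE
  if (anyNA(out)) incomplete <- TRUE
  attr(out, "subject_id") <- subject_id
  attr(out, "incomplete") <- incomplete
  out
}
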