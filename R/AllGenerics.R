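#' @include AllClasses.R
NULL

#' Accessors for Waveform and derived objects
#'
#' @param x an object.
#' @param ... unused.
#' @return `samples()` the numeric sample vector; `sampleRate()` the
#'   sampling rate in Hz; `duration()` the duration in seconds.
#' @name waveform-accessors
NULL

#' @rdname waveform-accessors
#' @export
setGeneric("samples", function(x, ...) standardGeneric("samples"))

#' @rdname waveform-accessors
#' @export
setGeneric("sampleRate", function(x, ...) standardGeneric("sampleRate"))

#' @rdname waveform-accessors
#' @export
setGeneric("duration", function(x, ...) standardGeneric("duration"))

#' @rdname waveform-accessors
#' @export
setMethod("samples", "Waveform", function(x, ...) x@samples)

#' @rdname waveform-accessors
#' @export
setMethod("sampleRate", "Waveform", function(x, ...) x@fs)

#' @rdname waveform-accessors
#' @export
setMethod("duration", "Waveform", function(x, ...) length(x@samples) / x@fs)

setMethod("show", "Waveform", function(object) {
  cat(sprintf("Waveform: %d samples @ %g Hz (%.3f s)%s\n",
    length(object@samples), object@fs, length(object@samples) / object@fs,
    if (nzchar(object@provenance)) paste0(" [", object@provenance, "]") else ""))
})

setMethod("show", "PitchTrack", function(object) {
  v <- object@f0 > 0
  cat(sprintf("PitchTrack: %d frames, %d voiced, mean F0 %.1f Hz\n",
    length(object@f0), sum(v), if (any(v)) mean(object@f0[v]) else NA_real_))
})

setMethod("show", "CycleSequence", function(object) {
  cat(sprintf("CycleSequence: %d cycles, mean period %.4f s\n",
    length(object@periods), mean(object@periods)))
})

setMethod("show", "SpectrogramMatrix", function(object) {
  cat(sprintf("SpectrogramMatrix (%s): %d frames x %d bins, %.3f s @ %g Hz\n",
    object@scale, nrow(object@values), ncol(object@values),
    if (length(object@times)) max(object@times) else 0, object@fs))
})

setMethod("show", "SpectralSummary", function(object) {
  cat(sprintf("SpectralSummary [%s] subject '%s': p = %d\n",
    object@kind, object@subject_id, length(object@mean_vec)))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult (%s): %d iterations, mean AUC %.3f (median %.3f, IQR %.3f)\n",
    object@model, length(object@auc), mean(object@auc),
    stats::median(object@auc), stats::IQR(object@auc)))
})

#' Summary statistics of an EvalResult
#'
#' @param object an [EvalResult-class].
#' @param ... unused.
#' @return named list with `mean`, `median`, `iqr`, `sd` and `n_iter`.
#' @export
setMethod("summary", "EvalResult", function(object, ...) {
  list(mean = mean(object@auc), median = stats::median(object@auc),
       iqr = stats::IQR(object@auc), sd = stats::sd(object@auc),
       n_iter = length(object@auc))
})

#' @rdname waveform-accessors
#' @export
setGeneric("aucValues", function(x, ...) standardGeneric("aucValues"))

#' @rdname waveform-accessors
#' @export
setMethod("aucValues", "EvalResult", function(x, ...) x@auc)
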