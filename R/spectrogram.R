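# Linear- and mel-scale spectrogram matrices, their 600x600 image
# rendering, and group-average difference maps.

#' Mel scale conversions
#'
#' `mel = 2595 * log10(1 + f / 700)` — approximately linear below 1 kHz
#' and logarithmic above; strictly increasing with exact inverse
#' [melToHz()].
#'
#' @param f frequency in Hz (>= 0).
#' @return mel value(s).
#' @examples
#' hzToMel(1000)  # ~ 999.99 mel: the near-identity at 1 kHz
#' @export
hzToMel <- function(f) {
  if (any(f < 0)) stop("frequency must be >= 0")
  2595 * log10(1 + f / 700)
}

#' @rdname hzToMel
#' @param mel mel value (>= 0).
#' @export
melToHz <- function(mel) {
  if (any(mel < 0)) stop("mel must be >= 0")
  700 * (10^(mel / 2595) - 1)
}

#' Short-time Fourier transform
#'
#' Hann-windowed STFT. With `center = FALSE` (linear-spectrogram recipe)
#' framing is no-padding with count `floor((n - win) / hop) + 1`; with
#' `center = TRUE` (mel recipe) the signal is zero-padded by `win / 2` on
#' both sides and the count is `floor(n / hop) + 1`.
#'
#' @param w a [Waveform-class].
#' @param win window length, samples.
#' @param hop hop, samples.
#' @param nfft FFT size (>= win; window is zero-padded).
#' @param center logical, center-padded framing.
#' @return List: `S` complex frames x (nfft/2 + 1) matrix, `times`,
#'   `freqs`.
#' @export
stft <- function(w, win = 1024L, hop = 256L, nfft = win, center = FALSE) {
  stopifnot(is(w, "Waveform"))
  x <- w@samples
  if (center) x <- c(numeric(win %/% 2L), x, numeric(win))
  n <- length(x)
  if (n < win) stop("input shorter than one analysis window")
  starts <- if (center) 1L + (seq_len(floor(length(w@samples) / hop) + 1L) - 1L) * hop
            else frameStarts(n, win, hop)
  starts <- starts[starts + win - 1L <= n]
  h <- hannWindow(win)
  n_bins <- nfft %/% 2L + 1L
  S <- matrix(0i, nrow = length(starts), ncol = n_bins)
  for (i in seq_along(starts)) {
    fr <- x[starts[i]:(starts[i] + win - 1L)] * h
    X <- stats::fft(c(fr, numeric(nfft - win)))
    S[i, ] <- X[1:n_bins]
  }
  offset <- if (center) -(win %/% 2L) else 0L
  list(S = S,
       times = (starts - 1L + offset + win / 2) / w@fs,
       freqs = (seq_len(n_bins) - 1L) * w@fs / nfft)
}

#' Linear-scale spectrogram matrix
#'
#' Hann window of 1024 samples, 75% overlap (hop 256), FFT size 1024,
#' no-padding framing; values are `10 log10(|S| / max |S|)` so the global
#' maximum is exactly 0 dB. At the 8820 Hz analysis rate a 1.5 s clip
#' yields 48 time windows.
#'
#' @param w a [Waveform-class] with at least `win` samples.
#' @param win,overlap,nfft STFT parameters (defaults 1024, 0.75, 1024).
#' @return A [SpectrogramMatrix-class] with `scale = "linear"`.
#' @export
linearSpectrogram <- function(w, win = 1024L, overlap = 0.75, nfft = 1024L) {
  hop <- as.integer(round(win * (1 - overlap)))
  st <- stft(w, win = win, hop = hop, nfft = nfft, center = FALSE)
  mag <- Mod(st$S)
  mx <- max(mag)
  if (mx <= 0) stop("all-zero input")
  vals <- 10 * log10(pmax(mag / mx, 1e-10))
  new("SpectrogramMatrix", values = vals, times = st$times, freqs = st$freqs,
      scale = "linear", fs = w@fs)
}

#' Mel-scale spectrogram matrix
#'
#' Hann window of 512 samples, 90% overlap resolved as hop
#' `floor(512 * 0.10) = 51` with center padding (frame count
#' `floor(n / hop) + 1`), FFT size 1024 and 256 triangular mel filters
#' over 0 to fs/2. Values are log mel energies normalized by the maximum
#' (`10 log10(M / max M)`, max exactly 0). At 8820 Hz a 1.5 s clip yields
#' 260 time windows.
#'
#' @param w a [Waveform-class] with at least `win` samples.
#' @param win,hop,nfft,n_mels parameters (defaults 512, 51, 1024, 256).
#' @return A [SpectrogramMatrix-class] with `scale = "mel"`; `freqs` holds
#'   the mel filter center frequencies in mel.
#' @export
melSpectrogram <- function(w, win = 512L, hop = 51L, nfft = 1024L,
                           n_mels = 256L) {
  if (length(w@samples) < win) stop("input shorter than one analysis window")
  st <- stft(w, win = win, hop = hop, nfft = nfft, center = TRUE)
  pow <- Mod(st$S)^2
  fb <- melFilterbank(n_mels, ncol(pow), w@fs, nfft)
  M <- pow %*% fb
  mx <- max(M)
  if (mx <= 0) stop("all-zero input")
  vals <- 10 * log10(pmax(M / mx, 1e-10))
  mel_pts <- seq(hzToMel(0), hzToMel(w@fs / 2), length.out = n_mels + 2L)
  new("SpectrogramMatrix", values = vals, times = st$times,
      freqs = mel_pts[2:(n_mels + 1L)], scale = "mel", fs = w@fs)
}

#' Render a spectrogram matrix as a 600x600 24-bit color image
#'
#' Deterministic mapping: values clamped to `[-80, 0]` dB, bilinear
#' resampling to the target size (frequency on the vertical axis, low
#' frequencies at the bottom), fixed perceptually-uniform colormap
#' (viridis). The colormap id is stamped into the object because
#' downstream image classifiers can be sensitive to it.
#'
#' @param m a [SpectrogramMatrix-class].
#' @param colormap colormap id understood by [viridisLite::viridis()]
#'   (default `"viridis"`).
#' @param size output image side length in pixels (default 600).
#' @param subject_id stored in the image metadata.
#' @return A [SpectrogramImage-class] (pixels in `[0, 1]`, size x size x 3).
#' @export
renderSpectrogramImage <- function(m, colormap = "viridis", size = 600L,
                                   subject_id = "subject") {
  stopifnot(is(m, "SpectrogramMatrix"))
  if (!length(m@values)) stop("empty spectrogram matrix")
  v <- pmin(pmax(m@values, -80), 0)
  v01 <- (v + 80) / 80
  # rows = frequency (flipped so low freq is at the bottom), cols = time
  grid <- resizeBilinear(t(v01)[rev(seq_len(ncol(v01))), , drop = FALSE],
                         size, size)
  pal <- grDevices::col2rgb(viridisLite::viridis(256L, option = colormap)) / 255
  idx <- pmin(pmax(round(grid * 255) + 1L, 1L), 256L)
  px <- array(0, dim = c(size, size, 3L))
  for (ch in 1:3) px[, , ch] <- matrix(pal[ch, idx], nrow = size)
  new("SpectrogramImage", pixels = px, colormap = colormap,
      subject_id = subject_id, scale = m@scale)
}

#' Write a rendered spectrogram image to disk
#'
#' PNG is the default (lossless, bit-deterministic); JPEG (quality 95) is
#' available for compatibility with pipelines expecting jpg input.
#'
#' @param img a [SpectrogramImage-class].
#' @param path output path; format chosen by extension (.png or .jpg).
#' @return `path`, invisibly.
#' @export
writeSpectrogramImage <- function(img, path) {
  stopifnot(is(img, "SpectrogramImage"))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    png::writePNG(img@pixels, path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("the 'jpeg' package is required to write JPEG images")
    jpeg::writeJPEG(img@pixels, path, quality = 0.95)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' Group-average spectrogram difference map
#'
#' Element-wise mean of the matrices in each group, then the difference
#' `mean(A) - mean(B)`. Used to visualize where (e.g. around F0 and the
#' first two formants) the PD group deviates from controls on average.
#'
#' @param group_a,group_b lists of [SpectrogramMatrix-class] objects of
#'   identical shape and scale.
#' @return A matrix (time x frequency) of average differences, with
#'   attributes `times` and `freqs` from the first input.
#' @export
averageSpectrogramDifference <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  all_m <- c(group_a, group_b)
  dims <- vapply(all_m, function(m) dim(m@values), integer(2))
  scales <- vapply(all_m, function(m) m@scale, character(1))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch between spectrogram matrices")
  if (length(unique(scales)) != 1L) stop("scale mismatch between groups")
  avg <- function(g) Reduce(`+`, lapply(g, function(m) m@values)) / length(g)
  d <- avg(group_a) - avg(group_b)
  attr(d, "times") <- group_a[[1L]]@times
  attr(d, "freqs") <- group_a[[1L]]@freqs
  d
}
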