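#' Construct a stimulus signal
#'
#' A uniformly sampled one-dimensional driver series (lip aperture area,
#' speech envelope, or any other regressor) with sample-rate metadata.
#'
#' @param values numeric vector of finite sample values.
#' @param fs sampling rate in Hz (> 0).
#' @param kind one of `"lip_area"`, `"audio_envelope"`, `"other"`.
#' @return an object of class `stimulus_signal`: a list with elements
#'   `values`, `fs`, `kind`.
#' @export
stimulus_signal <- function(values, fs, kind = c("other", "lip_area", "audio_envelope")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number", call. = FALSE)
  if (!all(is.finite(values)))
    stop("'values' must be finite", call. = FALSE)
  structure(list(values = values, fs = fs, kind = kind),
            class = "stimulus_signal")
}

#' @export
print.stimulus_signal <- function(x, ...) {
  cat(sprintf("<stimulus_signal> kind=%s fs=%g Hz n=%d (%.1f s)\n",
              x$kind, x$fs, length(x$values), length(x$values) / x$fs))
  invisible(x)
}

#' Construct an audio waveform
#'
#' @param samples numeric vector of audio samples.
#' @param fs sampling rate in Hz, typically 48000.
#' @return an object of class `audio_waveform`.
#' @export
audio_waveform <- function(samples, fs) {
  if (fs <= 0) stop("'fs' must be positive", call. = FALSE)
  structure(list(samples = as.numeric(samples), fs = fs),
            class = "audio_waveform")
}

#' @export
print.audio_waveform <- function(x, ...) {
  cat(sprintf("<audio_waveform> fs=%g Hz n=%d (%.2f s)\n",
              x$fs, length(x$samples), length(x$samples) / x$fs))
  invisible(x)
}

# Fourier-domain rate conversion.  Upsampling inserts zeros in the
# spectrum (exact band-limited interpolation); downsampling applies a
# brick-wall anti-alias response at 0.45 * target_fs before re-sampling
# the heavily oversampled smoothed series.  DC (hence the mean) is
# preserved exactly and constant inputs map to constant outputs.
.fft_resample <- function(x, fs, target_fs) {
  n <- length(x)
  n_out <- round(n * target_fs / fs)
  if (target_fs == fs) return(x)
  if (target_fs > fs) {
    X <- fft(x)
    Y <- complex(real = numeric(n_out))
    half <- floor(n / 2)
    Y[1:(half + 1L)] <- X[1:(half + 1L)]
    if (half > 0L) Y[(n_out - half + 1L):n_out] <- X[(n - half + 1L):n]
    if (n %% 2L == 0L) {
      # split the Nyquist bin symmetrically to keep the series real
      Y[half + 1L] <- Y[half + 1L] / 2
      Y[n_out - half + 1L] <- Conj(Y[half + 1L])
    }
    Re(fft(Y, inverse = TRUE)) / n
  } else {
    X <- fft(x)
    f <- (0:(n - 1L)) / n * fs
    f <- pmin(f, fs - f)
    X[f > 0.45 * target_fs] <- 0
    xs <- Re(fft(X, inverse = TRUE)) / n
    tt <- (0:(n_out - 1L)) / target_fs
    approx((0:(n - 1L)) / fs, xs, xout = tt, rule = 2)$y
  }
}

#' Resample a stimulus signal
#'
#' Anti-aliased sample-rate conversion. The lip aperture series (sampled at
#' the video frame rate, typically 25 Hz) and the speech envelope are
#' brought to the common analysis rate, 250 Hz, matching the rate of the
#' preprocessed neural recordings.
#'
#' @param x a [stimulus_signal()].
#' @param target_fs desired sampling rate in Hz.
#' @return a [stimulus_signal()] at `target_fs`; duration is preserved to
#'   within one sample and the mean is preserved exactly.
#' @export
resample_signal <- function(x, target_fs) {
  stopifnot(inherits(x, "stimulus_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("'target_fs' must be a single positive number", call. = FALSE)
  stimulus_signal(.fft_resample(x$values, x$fs, target_fs), target_fs, x$kind)
}
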