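#' Segmentation specification for Welch-type spectral estimation
#'
#' @param win_s segment length in seconds (default 1).
#' @param step_s step between segment onsets in seconds (default 0.5,
#'   i.e. 50 percent overlap).
#' @param taper `"hann"` for a single Hann taper per segment, or `"sine"`
#'   for a sine multitaper family.
#' @param n_tapers number of tapers when `taper = "sine"`; ignored for
#'   `"hann"`.
#' @return an object of class `segment_spec`.
#' @export
segment_spec <- function(win_s = 1, step_s = 0.5, taper = c("hann", "sine"),
                         n_tapers = 3L) {
  taper <- match.arg(taper)
  if (!(step_s > 0 && step_s <= win_s))
    stop("need 0 < step_s <= win_s", call. = FALSE)
  structure(list(win_s = win_s, step_s = step_s, taper = taper,
                 n_tapers = if (taper == "sine") as.integer(n_tapers) else 1L),
            class = "segment_spec")
}

# taper matrix: one column per taper, unit total energy
.tapers <- function(n, spec) {
  if (spec$taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
    matrix(w / sqrt(sum(w^2)), ncol = 1L)
  } else {
    k <- seq_len(spec$n_tapers)
    t <- seq_len(n)
    sapply(k, function(j) sqrt(2 / (n + 1)) * sin(pi * j * t / (n + 1)))
  }
}

.seg_starts <- function(n_samples, fs, spec) {
  n_win <- round(spec$win_s * fs)
  n_step <- round(spec$step_s * fs)
  if (n_samples < n_win)
    stop("series shorter than one segment window", call. = FALSE)
  seq(1L, n_samples - n_win + 1L, by = n_step)
}

#' Cut a series into overlapping demeaned, tapered segments
#'
#' The analysis convention is 1-s segments overlapping by 0.5 s; each
#' segment is demeaned and tapered before Fourier transformation.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param spec a [segment_spec()].
#' @return a numeric matrix, segment length x number of segments, with
#'   attribute `"taper"` holding the taper matrix actually applied (first
#'   taper only; multitaper expansion happens inside the estimators).
#' @export
segment_signal <- function(x, fs, spec = segment_spec()) {
  starts <- .seg_starts(length(x), fs, spec)
  n_win <- round(spec$win_s * fs)
  tap <- .tapers(n_win, spec)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + n_win - 1L)]
    (seg - mean(seg)) * tap[, 1L]
  }, numeric(n_win))
  segs <- matrix(segs, nrow = n_win)
  attr(segs, "taper") <- tap
  attr(segs, "n_segments") <- length(starts)
  segs
}

# Complex Fourier coefficients of all demeaned, tapered segments.
# Returns a bins x (segments * tapers) complex matrix plus the frequency
# axis. Used by cross_spectra (all bins) and by the single-bin fast path.
.seg_fft <- function(x, fs, spec) {
  starts <- .seg_starts(length(x), fs, spec)
  n_win <- round(spec$win_s * fs)
  tap <- .tapers(n_win, spec)
  n_tap <- ncol(tap)
  segmat <- vapply(starts, function(s) {
    seg <- x[s:(s + n_win - 1L)]
    seg - mean(seg)
  }, numeric(n_win))
  segmat <- matrix(segmat, nrow = n_win)
  coefs <- vector("list", n_tap)
  for (k in seq_len(n_tap)) coefs[[k]] <- mvfft(segmat * tap[, k])
  coefs <- do.call(cbind, coefs)
  n_keep <- floor(n_win / 2) + 1L
  list(coefs = coefs[seq_len(n_keep), , drop = FALSE],
       freqs = (seq_len(n_keep) - 1L) * fs / n_win,
       n_segments = length(starts))
}

# Fourier coefficient of each segment at one frequency bin only
# (direct inner product; avoids the full FFT when mapping many voxels).
.seg_coef_bin <- function(x, fs, freq, spec) {
  starts <- .seg_starts(length(x), fs, spec)
  n_win <- round(spec$win_s * fs)
  tap <- .tapers(n_win, spec)
  k <- round(freq * spec$win_s)
  if (k > floor(n_win / 2))
    stop("frequency above Nyquist for this segment length", call. = FALSE)
  basis <- exp(-2i * pi * k * (0:(n_win - 1L)) / n_win)
  segmat <- vapply(starts, function(s) {
    seg <- x[s:(s + n_win - 1L)]
    seg - mean(seg)
  }, numeric(n_win))
  segmat <- matrix(segmat, nrow = n_win)
  out <- vector("list", ncol(tap))
  for (j in seq_len(ncol(tap))) out[[j]] <- crossprod(segmat * tap[, j], basis)[, 1L]
  unlist(out)
}

# design a zero-phase band filter; low edge clipped at 0 collapses to a
# low-pass design (stable for the low analysis bands)
.design_band <- function(fs, center, halfwidth, order = 4L) {
  lo <- center - halfwidth
  hi <- center + halfwidth
  if (hi >= fs / 2)
    stop("band edge at or above Nyquist", call. = FALSE)
  flt <- if (lo <= 0.05) {
    butter(order, hi / (fs / 2), type = "low")
  } else {
    butter(order, c(lo, hi) / (fs / 2), type = "pass")
  }
  if (max(Mod(polyroot(rev(flt$a)))) >= 1)
    stop(sprintf(
      "unstable band-pass design (center %g Hz, halfwidth %g Hz at fs %g Hz); widen the band or reduce the order",
      center, halfwidth, fs), call. = FALSE)
  flt
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth filter applied forward and reverse
#' (zero phase). Bands are specified as center +/- halfwidth, the
#' convention used throughout the frequency-resolved coherence analysis
#' (center 1..7 Hz, halfwidth 3 Hz); a low band edge at or below zero is
#' clipped, collapsing the design to a low-pass at the upper edge.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param center band center in Hz.
#' @param halfwidth half-bandwidth in Hz (default 3).
#' @param order filter order (default 4).
#' @return filtered series, same length as `x`.
#' @export
bandpass <- function(x, fs, center, halfwidth = 3, order = 4L) {
  flt <- .design_band(fs, center, halfwidth, order)
  as.numeric(filtfilt(flt, x))
}

#' Welch-averaged auto- and cross-spectra of two or three series
#'
#' Spectra are averaged over demeaned, tapered, overlapping segments
#' (1-s windows overlapping 0.5 s by default, giving 1 Hz resolution).
#' With a third series `z` present, the conditioner terms needed for
#' partial coherence are included.
#'
#' @param x,y numeric series of equal length.
#' @param z optional conditioning series (e.g. the speech envelope when
#'   partialling sound out of lip-brain coherence).
#' @param fs sampling rate in Hz.
#' @param spec a [segment_spec()].
#' @return an object of class `cross_spectra`: list with `freqs`, real
#'   `S_xx`, `S_yy` (and `S_zz`), complex `S_xy` (and `S_xz`, `S_zy`),
#'   and `n_segments`.
#' @export
cross_spectra <- function(x, y, z = NULL, fs, spec = segment_spec()) {
  if (length(x) != length(y) || (!is.null(z) && length(z) != length(x)))
    stop("series must have equal length", call. = FALSE)
  fx <- .seg_fft(x, fs, spec)
  fy <- .seg_fft(y, fs, spec)
  sc <- 1 / (fs * fx$n_segments)   # density scale; cancels in coherence
  out <- list(freqs = fx$freqs,
              S_xx = rowMeans(Mod(fx$coefs)^2) / fs,
              S_yy = rowMeans(Mod(fy$coefs)^2) / fs,
              S_xy = rowMeans(fx$coefs * Conj(fy$coefs)) / fs,
              n_segments = fx$n_segments)
  if (!is.null(z)) {
    fz <- .seg_fft(z, fs, spec)
    out$S_zz <- rowMeans(Mod(fz$coefs)^2) / fs
    out$S_xz <- rowMeans(fx$coefs * Conj(fz$coefs)) / fs
    out$S_zy <- rowMeans(fz$coefs * Conj(fy$coefs)) / fs
  }
  structure(out, class = "cross_spectra")
}

.new_coherence_spectrum <- function(C, freqs, kind, conditioned_on = NULL,
                                    flagged = NULL) {
  structure(list(freqs = freqs, C = C, kind = kind,
                 conditioned_on = conditioned_on,
                 flagged = flagged),
            class = "coherence_spectrum")
}

#' Magnitude-squared coherence from averaged cross-spectra
#'
#' `C_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))`, the frequency-domain
#' squared-correlation between two series, bounded in `[0, 1]`.
#'
#' @param cs a [cross_spectra()] object with at least 2 segments.
#' @return an object of class `coherence_spectrum` with elements `freqs`,
#'   `C`, `kind = "coherence"`. Frequencies with zero power in either
#'   series get `C = 0` and are listed in the `flagged` element.
#' @export
coherence <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  if (cs$n_segments < 2L) stop("need at least 2 segments", call. = FALSE)
  denom <- cs$S_xx * cs$S_yy
  C <- ifelse(denom > 0, Mod(cs$S_xy)^2 / denom, 0)
  C <- pmin(pmax(C, 0), 1)
  .new_coherence_spectrum(C, cs$freqs, "coherence",
                          flagged = which(denom <= 0))
}

#' Partial coherence, conditioning out a third series
#'
#' With coherency `R_ab(f) = S_ab / sqrt(S_aa S_bb)`, the coherence
#' between `x` and `y` after removing the linear contribution of `z` at
#' each frequency is
#' `C_xy|z = |R_xy - R_xz R_zy|^2 / ((1 - |R_xz|^2)(1 - |R_zy|^2))`.
#' This equals the coherence of the per-frequency residuals of `x` and
#' `y` after projecting out `z`. It is the estimator used to remove the
#' acoustic envelope's contribution from lip-brain coherence.
#'
#' @param cs a [cross_spectra()] computed with a conditioner `z`.
#' @return a `coherence_spectrum` with `kind = "partial_coherence"`.
#'   Frequencies where the conditioner is (near-)collinear with `x` or
#'   `y` (`|R|^2 > 1 - 1e-6`) are returned as `NA` and flagged.
#' @export
partial_coherence <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  if (is.null(cs$S_zz))
    stop("cross_spectra lacks a conditioning series; pass z to cross_spectra()",
         call. = FALSE)
  if (cs$n_segments < 3L) stop("need at least 3 segments", call. = FALSE)
  R_xy <- cs$S_xy / sqrt(cs$S_xx * cs$S_yy)
  R_xz <- cs$S_xz / sqrt(cs$S_xx * cs$S_zz)
  R_zy <- cs$S_zy / sqrt(cs$S_zz * cs$S_yy)
  d1 <- 1 - Mod(R_xz)^2
  d2 <- 1 - Mod(R_zy)^2
  bad <- !is.finite(d1) | !is.finite(d2) | d1 < 1e-6 | d2 < 1e-6
  C <- Mod(R_xy - R_xz * R_zy)^2 / (d1 * d2)
  C <- pmin(pmax(C, 0), 1)
  C[bad] <- NA_real_
  .new_coherence_spectrum(C, cs$freqs, "partial_coherence",
                          conditioned_on = "z", flagged = which(bad))
}

#' Time-shift surrogate of a driver signal
#'
#' Circularly shifts the driver by `shift_s` seconds (default 30 s).
#' The shift preserves the amplitude spectrum exactly but destroys the
#' temporal alignment with any other signal, so coherence computed
#' against the shifted driver estimates the chance-level (bias) floor
#' of the estimator for that condition.
#'
#' @param x a [stimulus_signal()].
#' @param shift_s shift in seconds; must be shorter than the series.
#' @return a shifted [stimulus_signal()].
#' @export
surrogate_driver <- function(x, shift_s = 30) {
  stopifnot(inherits(x, "stimulus_signal"))
  n <- length(x$values)
  k <- round(shift_s * x$fs)
  if (k >= n) stop("shift must be shorter than the series", call. = FALSE)
  if (k == 0L) return(x)
  stimulus_signal(c(x$values[(n - k + 1L):n], x$values[1:(n - k)]),
                  x$fs, x$kind)
}

# single-bin (partial) coherence from segment coefficients
.coh_from_coefs <- function(a, b, cz = NULL) {
  Sxx <- mean(Mod(a)^2); Syy <- mean(Mod(b)^2)
  if (Sxx <= 0 || Syy <= 0) return(0)
  Sxy <- mean(a * Conj(b))
  if (is.null(cz)) return(min(1, Mod(Sxy)^2 / (Sxx * Syy)))
  Szz <- mean(Mod(cz)^2)
  if (Szz <= 0) return(min(1, Mod(Sxy)^2 / (Sxx * Syy)))
  R_xy <- Sxy / sqrt(Sxx * Syy)
  R_xz <- mean(a * Conj(cz)) / sqrt(Sxx * Szz)
  R_zy <- mean(cz * Conj(b)) / sqrt(Szz * Syy)
  d1 <- 1 - Mod(R_xz)^2; d2 <- 1 - Mod(R_zy)^2
  if (d1 < 1e-6 || d2 < 1e-6) return(NA_real_)
  min(1, max(0, Mod(R_xy - R_xz * R_zy)^2 / (d1 * d2)))
}

#' Voxel-by-frequency (partial) coherence map
#'
#' For each voxel series and each analysis frequency, both the brain
#' series and the driver are band-pass filtered at center +/- `halfwidth`
#' Hz (zero-phase Butterworth), segmented, and the (partial) coherence is
#' evaluated at the center frequency bin. This produces the volumetric
#' entrainment map for one subject and condition.
#'
#' @param brain numeric matrix, voxels x samples.
#' @param driver a [stimulus_signal()] sharing the sampling rate.
#' @param fs sampling rate in Hz of `brain` (must equal `driver$fs`).
#' @param conditioner optional [stimulus_signal()] to partial out (the
#'   acoustic envelope); when present the map holds partial coherence.
#' @param freqs integer analysis frequencies in Hz (default 1:7).
#' @param halfwidth band half-width in Hz (default 3).
#' @param spec a [segment_spec()].
#' @param prefiltered set `TRUE` when `brain` rows are already band-pass
#'   filtered at the single frequency in `freqs` (used by the pipeline
#'   after beamforming, where filtering precedes reconstruction).
#' @return a voxels x frequencies matrix of class `coherence_map` with
#'   attributes `freqs`, `kind`, `conditioned_on`.
#' @export
coherence_map <- function(brain, driver, fs, conditioner = NULL,
                          freqs = 1:7, halfwidth = 3,
                          spec = segment_spec(), prefiltered = FALSE) {
  stopifnot(is.matrix(brain), inherits(driver, "stimulus_signal"))
  if (driver$fs != fs) stop("driver and brain sampling rates differ", call. = FALSE)
  if (!is.null(conditioner) && conditioner$fs != fs)
    stop("conditioner sampling rate differs", call. = FALSE)
  if (ncol(brain) != length(driver$values))
    stop("brain and driver lengths differ", call. = FALSE)
  if (prefiltered && length(freqs) != 1L)
    stop("'prefiltered' requires a single analysis frequency", call. = FALSE)
  out <- matrix(NA_real_, nrow(brain), length(freqs))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    dflt <- bandpass(driver$values, fs, f, halfwidth)
    dcoef <- .seg_coef_bin(dflt, fs, f, spec)
    ccoef <- NULL
    if (!is.null(conditioner)) {
      cflt <- bandpass(conditioner$values, fs, f, halfwidth)
      ccoef <- .seg_coef_bin(cflt, fs, f, spec)
    }
    for (v in seq_len(nrow(brain))) {
      bx <- if (prefiltered) brain[v, ] else bandpass(brain[v, ], fs, f, halfwidth)
      bcoef <- .seg_coef_bin(bx, fs, f, spec)
      out[v, j] <- .coh_from_coefs(bcoef, dcoef, ccoef)
    }
  }
  structure(out, class = c("coherence_map", "matrix"),
            freqs = freqs,
            kind = if (is.null(conditioner)) "coherence" else "partial_coherence",
            conditioned_on = if (is.null(conditioner)) NULL else conditioner$kind)
}
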