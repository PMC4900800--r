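# Independent oracles and small fixture builders used across the suite.

# Band-limited noise pair y = x + scaled independent noise with a given
# in-band SNR; coherence should equal SNR / (1 + SNR).
make_snr_pair <- function(n, fs, band = c(1, 7), snr = 1) {
  bp <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bp, rnorm(n)))
  nn <- as.numeric(signal::filtfilt(bp, rnorm(n)))
  y <- x + nn * sd(x) / sd(nn) / sqrt(snr)
  list(x = x, y = y)
}

# Brute-force Benjamini-Hochberg: reject the first k ordered p-values
# where k is the largest index with p_(k) <= q * k / m.
bh_reject_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- suppressWarnings(max(which(ps <= q * seq_len(m) / m)))
  rej <- logical(m)
  if (is.finite(k)) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Residual-projection partial coherence: per frequency, project z out of
# the segment Fourier coefficients of x and y by complex least squares,
# then take the ordinary coherence of the residuals. Independent route
# to the conditioned-coherency identity.
partial_coherence_residual_oracle <- function(x, y, z, fs,
                                              spec = segment_spec()) {
  fx <- avcoh:::.seg_fft(x, fs, spec)
  fy <- avcoh:::.seg_fft(y, fs, spec)
  fz <- avcoh:::.seg_fft(z, fs, spec)
  nb <- length(fx$freqs)
  C <- numeric(nb)
  for (b in seq_len(nb)) {
    a <- fx$coefs[b, ]; bb <- fy$coefs[b, ]; cz <- fz$coefs[b, ]
    pz <- sum(Mod(cz)^2)
    ra <- a - cz * sum(a * Conj(cz)) / pz
    rb <- bb - cz * sum(bb * Conj(cz)) / pz
    C[b] <- Mod(mean(ra * Conj(rb)))^2 /
      (mean(Mod(ra)^2) * mean(Mod(rb)^2))
  }
  list(freqs = fx$freqs, C = C)
}

# Fraction of (non-DC) periodogram power below a frequency cutoff.
power_fraction_below <- function(x, fs, f_cut) {
  x <- x - mean(x)
  P <- Mod(fft(x))^2
  n <- length(x)
  f <- (0:(n - 1)) * fs / n
  keep <- f > 0 & f <= fs / 2
  sum(P[keep & f < f_cut]) / sum(P[keep])
}

# Ellipse mask frames with an independently jittered major axis: the
# area tracks the driving series exactly while the horizontal semi-axis
# carries unrelated noise (minor axis then absorbs the area signal).
make_jittered_axis_masks <- function(area, shape = c(128L, 128L),
                                     a0 = 45) {
  h <- shape[1L]; w <- shape[2L]
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  aj <- a0 * (1 + 0.15 * as.numeric(stats::filter(rnorm(length(area)),
                                                  rep(1 / 4, 4),
                                                  circular = TRUE)))
  bj <- area / (pi * aj)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  arr <- array(FALSE, c(h, w, length(area)))
  for (i in seq_along(area))
    arr[, , i] <- ((xs - cx) / aj[i])^2 + ((ys - cy) / bj[i])^2 <= 1
  arr
}
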