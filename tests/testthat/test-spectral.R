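fs <- 250

test_that("band-pass keeps in-band tones and rejects out-of-band ones", {
  tt <- (0:(fs * 20 - 1)) / fs
  tone4 <- sin(2 * pi * 4 * tt)
  y <- bandpass(tone4, fs, center = 4, halfwidth = 3)
  mid <- (fs * 2):(fs * 18)
  expect_equal(sd(y[mid]), sd(tone4[mid]), tolerance = 0.05)

  tone20 <- sin(2 * pi * 20 * tt)
  y20 <- bandpass(tone20, fs, center = 4, halfwidth = 3)
  expect_lt(sd(y20[mid]), 0.1 * sd(tone20[mid]))

  # forward-reverse filtering gives a symmetric (zero-phase) response
  imp <- numeric(fs * 4); imp[fs * 2] <- 1
  h <- bandpass(imp, fs, center = 4, halfwidth = 3)
  k <- 50
  expect_equal(h[fs * 2 + seq_len(k)], h[fs * 2 - seq_len(k)],
               tolerance = 1e-4)

  expect_error(bandpass(tone4, fs, center = 124, halfwidth = 3), "Nyquist")
})

test_that("segmentation counts windows and demeans them", {
  x <- rnorm(fs * 10)
  segs <- segment_signal(x, fs)
  expect_equal(attr(segs, "n_segments"), 19)
  expect_equal(nrow(segs), 250)

  one <- segment_signal(rnorm(fs), fs)
  expect_equal(attr(one, "n_segments"), 1)

  const <- segment_signal(rep(5, fs * 3), fs)
  expect_true(all(const == 0))

  expect_error(segment_signal(rnorm(100), fs), "shorter")
})

test_that("cross-spectra have the expected structure and phase", {
  set.seed(11)
  x <- rnorm(fs * 60)
  cs <- cross_spectra(x, x, fs = fs)
  expect_true(all(abs(Im(cs$S_xy)) < 1e-12 * max(Mod(cs$S_xy))))
  expect_equal(Re(cs$S_xy), cs$S_xx, tolerance = 1e-12)

  # independent signals: coherence magnitude ~ 1/M
  y <- rnorm(fs * 60)
  csi <- cross_spectra(x, y, fs = fs)
  chat <- Mod(csi$S_xy)^2 / (csi$S_xx * csi$S_yy)
  expect_lt(mean(chat[2:100]), 4 / csi$n_segments)

  # a pure delay of y shows up as a linear phase at the tone frequency:
  # with S_xy = X conj(Y) and y(t) = x(t - lag), Arg S_xy = +2*pi*f*lag
  tt <- (0:(fs * 60 - 1)) / fs
  lag_s <- 0.02
  xs <- sin(2 * pi * 4 * tt) + 0.05 * rnorm(length(tt))
  ys <- sin(2 * pi * 4 * (tt - lag_s)) + 0.05 * rnorm(length(tt))
  csl <- cross_spectra(xs, ys, fs = fs)
  ph <- Arg(csl$S_xy[csl$freqs == 4])
  expect_equal(ph, 2 * pi * 4 * lag_s, tolerance = pi / 180)

  expect_error(cross_spectra(x, y[-1], fs = fs), "equal length")
})

test_that("coherence is bounded, exact for self, and calibrated for SNR", {
  set.seed(2)
  pair <- make_snr_pair(fs * 300, fs, snr = 1)
  cs <- cross_spectra(pair$x, pair$y, fs = fs)
  co <- coherence(cs)
  expect_true(all(co$C >= 0 & co$C <= 1))
  expect_equal(mean(co$C[co$freqs %in% 2:6]), 0.5, tolerance = 0.1)

  self <- coherence(cross_spectra(pair$x, pair$x, fs = fs))
  expect_true(all(abs(self$C[2:100] - 1) < 1e-10))
})

test_that("coherence bias for independent signals shrinks with segments", {
  set.seed(3)
  bias_at <- function(dur_s) {
    co <- coherence(cross_spectra(rnorm(fs * dur_s), rnorm(fs * dur_s),
                                  fs = fs))
    mean(co$C[2:100])
  }
  b20 <- bias_at(10.5)    # ~20 segments
  b100 <- bias_at(50.5)   # ~100 segments
  expect_gt(b20, b100)
  expect_lt(b100, 0.03)
})

test_that("coherence and partial coherence are scale invariant", {
  set.seed(4)
  x <- rnorm(fs * 30); y <- rnorm(fs * 30); z <- rnorm(fs * 30)
  c1 <- coherence(cross_spectra(x, y, z, fs = fs))
  p1 <- partial_coherence(cross_spectra(x, y, z, fs = fs))
  c2 <- coherence(cross_spectra(5.3 * x, 0.02 * y, 7 * z, fs = fs))
  p2 <- partial_coherence(cross_spectra(5.3 * x, 0.02 * y, 7 * z, fs = fs))
  expect_equal(c1$C, c2$C, tolerance = 1e-10)
  expect_equal(p1$C, p2$C, tolerance = 1e-10)
})

test_that("partial coherence cancels common drive and keeps genuine coupling", {
  set.seed(5)
  n <- fs * 120
  z <- rnorm(n)
  a <- sqrt(sqrt(2) - 1)       # population C_xy = 0.5
  x <- z + a * rnorm(n)
  y <- z + a * rnorm(n)
  cs <- cross_spectra(x, y, z, fs = fs)
  cxy <- coherence(cs)
  pxy <- partial_coherence(cs)
  sel <- 2:100
  expect_gt(mean(cxy$C[sel]), 0.4)
  expect_lt(mean(pxy$C[sel]), 0.05)

  # independence limit: conditioning on an unrelated signal changes little
  w <- rnorm(n)
  cs2 <- cross_spectra(x, y, w, fs = fs)
  expect_equal(mean(partial_coherence(cs2)$C[sel]),
               mean(coherence(cs2)$C[sel]), tolerance = 0.05)

  # identity pair stays ~1 under conditioning
  cs3 <- cross_spectra(x, x, z, fs = fs)
  expect_true(all(partial_coherence(cs3)$C[sel] > 0.99))

  expect_error(partial_coherence(cross_spectra(x, y, fs = fs)), "conditioning")
})

test_that("partial coherence matches the residual-projection oracle", {
  set.seed(6)
  for (rep in 1:20) {
    n <- fs * 8
    z <- rnorm(n)
    x <- 0.6 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    est <- partial_coherence(cross_spectra(x, y, z, fs = fs))
    orc <- partial_coherence_residual_oracle(x, y, z, fs)
    ok <- !is.na(est$C)
    expect_lt(max(abs(est$C[ok] - orc$C[ok])), 1e-6)
  }
})

test_that("surrogate shifting preserves spectra and breaks alignment", {
  set.seed(7)
  lip <- gen_lip_driver(120, fs, seed = 30)
  expect_identical(surrogate_driver(lip, 0)$values, lip$values)
  sur <- surrogate_driver(lip, 30)
  expect_equal(Mod(fft(sur$values)), Mod(fft(lip$values)), tolerance = 1e-9)
  expect_error(surrogate_driver(lip, 200), "shorter")

  env <- gen_coupled_envelope(lip, 0.6, c(4, 8), seed = 31)
  coupled <- coherence_map(matrix(env$values, 1), lip, fs, freqs = 6)
  broken <- coherence_map(matrix(env$values, 1), sur, fs, freqs = 6)
  expect_gt(coupled[1, 1], 0.4)
  expect_lt(broken[1, 1], 0.05)
})

test_that("coherence maps localize coupling across voxels and frequencies", {
  set.seed(8)
  lip <- gen_lip_driver(120, fs, seed = 40)
  env <- gen_coupled_envelope(lip, 0.6, c(3, 5), seed = 41)
  brain <- rbind(rnorm(length(lip$values)),
                 env$values,
                 rnorm(length(lip$values)))
  cm <- coherence_map(brain, lip, fs, freqs = c(2, 4, 6))
  expect_equal(dim(cm), c(3L, 3L))
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(which.max(cm[, 2]), 2L)
  expect_gt(cm[2, 2], 0.4)
  expect_lt(max(cm[c(1, 3), ]), 0.1)

  # a voxel's own series has unit coherence with itself at every band
  own <- coherence_map(brain[2, , drop = FALSE],
                       stimulus_signal(brain[2, ], fs), fs, freqs = c(2, 4))
  expect_true(all(own > 0.999))
})
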