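fs <- 250

test_that("the lip driver has the expected low-frequency spectrum", {
  lip <- gen_lip_driver(300, fs, seed = 1)
  expect_true(all(lip$values >= 0))

  # smoothed periodogram peak in the 0-4 Hz range
  sp <- stats::spec.pgram(stats::ts(lip$values - mean(lip$values),
                                    frequency = fs),
                          spans = 31, plot = FALSE)
  peak <- sp$freq[which.max(sp$spec)]
  expect_gte(peak, 0)
  expect_lte(peak, 4)

  # direct periodogram integration: > 90 % of power below 7 Hz
  lip2 <- gen_lip_driver(300, fs, seed = 2)
  expect_gt(power_fraction_below(lip2$values, fs, 7), 0.9)

  # seeded determinism
  again <- gen_lip_driver(300, fs, seed = 1)
  expect_identical(lip$values, again$values)

  expect_error(gen_lip_driver(30, fs, seed = 1), "duration")
  expect_error(gen_lip_driver(300, 20, seed = 1), "fs")
})

test_that("coupled envelopes hit their target coherence in-band", {
  lip <- gen_lip_driver(300, fs, seed = 3)

  env0 <- gen_coupled_envelope(lip, 0, c(4, 8), seed = 4)
  cm0 <- coherence_map(matrix(env0$values, 1), lip, fs, freqs = 5:7)
  expect_lt(max(cm0), 0.03)   # independent-signal bias ceiling

  for (target in c(0.2, 0.5, 0.8)) {
    env <- gen_coupled_envelope(lip, target, c(4, 8), seed = 5)
    cm <- coherence_map(matrix(env$values, 1), lip, fs, freqs = 5:7)
    expect_equal(mean(cm), target, tolerance = 0.1)
  }

  env9 <- gen_coupled_envelope(lip, 0.9, c(4, 8), seed = 6)
  inb <- coherence_map(matrix(env9$values, 1), lip, fs, freqs = 6)
  outb <- coherence_map(matrix(env9$values, 1), lip, fs, freqs = 15)
  expect_gt(inb[1, 1], outb[1, 1])

  expect_error(gen_coupled_envelope(lip, 1.2, c(4, 8), seed = 1), "target")
  expect_error(gen_coupled_envelope(lip, 0.5, c(4, 200), seed = 1), "band")
})

test_that("mask areas track the requested series within tolerance", {
  m <- gen_lip_masks(rep(4000, 100), 25, image_shape = c(128L, 128L),
                     seed = 7)
  counts <- apply(m, 3, sum)
  expect_true(all(abs(counts - 4000) <= 80))
})

test_that("source-level coupling is calibrated at the coupling frequency", {
  # noiseless 1-voxel, 1-sensor study: sensor = scaled source
  lf1 <- leadfield_model(matrix(1, 1, 1), matrix(c(0, 0, 0), 1, 3), 8)
  for (strength in c(0.2, 0.5, 0.8)) {
    cfg <- synthetic_config(n_subjects = 1, n_voxels = 1L, n_sensors = 1L,
                            duration_s = 300, coupled_voxels = 1L,
                            coupling_strength = c(av_congruent = strength),
                            noise_sd = 0, seed = 8)
    lip <- gen_lip_driver(300, fs, seed = 9)
    X <- gen_subject_sensors(cfg, lip, NULL, lf1, subject_seed = 10)
    cm <- coherence_map(X, lip, fs, freqs = 4)
    expect_equal(cm[1, 1], strength, tolerance = 0.1)
  }

  # zero coupling: coherence at the estimator bias floor
  cfg0 <- synthetic_config(n_subjects = 1, n_voxels = 1L, n_sensors = 1L,
                           duration_s = 300, coupled_voxels = 1L,
                           coupling_strength = c(av_congruent = 0),
                           noise_sd = 0, seed = 8)
  lip <- gen_lip_driver(300, fs, seed = 9)
  X0 <- gen_subject_sensors(cfg0, lip, NULL, lf1, subject_seed = 10)
  cm0 <- coherence_map(X0, lip, fs, freqs = 1:7)
  expect_lt(max(cm0), 0.03)
})

test_that("subject seeding changes noise but not the recorded truth", {
  cfg <- synthetic_config(n_subjects = 2, n_voxels = 6L, n_sensors = 4L,
                          duration_s = 60, coupled_voxels = 2L,
                          coupling_strength = c(av_congruent = 0.5),
                          seed = 11)
  lip <- gen_lip_driver(60, fs, seed = 12)
  lf <- gen_leadfield(4, 6, seed = 13)
  a <- gen_subject_sensors(cfg, lip, NULL, lf, subject_seed = 100)
  b <- gen_subject_sensors(cfg, lip, NULL, lf, subject_seed = 101)
  a2 <- gen_subject_sensors(cfg, lip, NULL, lf, subject_seed = 100)
  expect_false(isTRUE(all.equal(a, b, check.attributes = FALSE)))
  expect_identical(a, a2)
  expect_equal(attr(a, "truth"), attr(b, "truth"))

  bad_lf <- gen_leadfield(4, 7, seed = 13)
  expect_error(gen_subject_sensors(cfg, lip, NULL, bad_lf, 1),
               "dimensions")
})

test_that("sensor variance decomposes into projected source and noise power", {
  cfg <- synthetic_config(n_subjects = 1, n_voxels = 24L, n_sensors = 12L,
                          duration_s = 240, coupled_voxels = integer(0),
                          coupling_strength = c(av_congruent = 0),
                          noise_sd = 1.5, seed = 14)
  lip <- gen_lip_driver(240, fs, seed = 15)
  lf <- gen_leadfield(12, 24, seed = 16)
  X <- gen_subject_sensors(cfg, lip, NULL, lf, subject_seed = 17)
  predicted <- rowSums(lf$L^2) + 1.5^2
  ratio <- apply(X, 1, var) / predicted
  expect_true(all(abs(ratio - 1) < 0.05))
})

test_that("behavioral scores follow the coupling with 10-point granularity", {
  acc <- gen_behavior(rep(0.5, 50), slope = 0, noise_sd = 10, seed = 18)
  expect_true(all(acc %% 10 == 0))
  expect_true(all(acc >= 0 & acc <= 100))

  set.seed(19)
  coup <- rnorm(200, 0.5, 0.1)
  acc0 <- gen_behavior(coup, slope = 0, noise_sd = 10, seed = 20)
  expect_lt(abs(cor(coup, acc0)), 0.2)

  accs <- gen_behavior(coup, slope = 45, noise_sd = 10, seed = 21)
  expect_gt(cor(coup, accs), 0.2)

  expect_error(gen_behavior(coup, Inf, 10, 1), "finite")
})

test_that("whole studies are deterministic and round-trip to disk", {
  cfg <- synthetic_config(n_subjects = 2, n_voxels = 12L, n_sensors = 6L,
                          duration_s = 60, coupled_voxels = 3L,
                          coupling_subject_sd = 0.05, seed = 22)
  st1 <- gen_synthetic_study(cfg)
  st2 <- gen_synthetic_study(cfg)
  expect_identical(st1$sensor_data, st2$sensor_data)
  expect_identical(st1$behavior, st2$behavior)
  expect_true(all(st1$behavior$accuracy %% 10 == 0))
  expect_equal(sort(unique(st1$truth$voxel)), 3)

  dir <- withr::local_tempdir()
  write_study(st1, dir)
  back <- read_study(dir)
  expect_equal(back$lip$values, st1$lip$values)
  expect_identical(back$sensor_data, st1$sensor_data)
  expect_equal(back$behavior, st1$behavior)
  expect_equal(back$leadfield$L, st1$leadfield$L)
  expect_equal(back$config$coupling_strength, cfg$coupling_strength)
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(coupling_strength = c(a = 1.2)), "\\[0, 1\\]")
  expect_error(synthetic_config(fs = 6, coupling_freq = 4), "fs")
  expect_error(synthetic_config(n_voxels = 10L, coupled_voxels = 12L),
               "range")
})
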