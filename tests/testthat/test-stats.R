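grid_coords <- function(nx, ny, nz, spacing = 8)
  as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny),
                        z = seq_len(nz))) * spacing

test_that("Gaussian smoothing preserves mass, constants and the limit", {
  co <- grid_coords(9, 9, 9)
  v <- numeric(nrow(co))
  center <- which(co[, 1] == 40 & co[, 2] == 40 & co[, 3] == 40)
  v[center] <- 1
  s <- smooth_map(v, co, 10)
  expect_equal(sum(s), 1, tolerance = 1e-10)   # interior delta: mass kept
  expect_lt(max(s), 1)
  expect_equal(which.max(s), center)

  const <- smooth_map(rep(2.5, nrow(co)), co, 10)
  expect_equal(const, rep(2.5, nrow(co)), tolerance = 1e-12)

  expect_identical(smooth_map(v, co, 0), v)

  bad <- co; bad[2, 1] <- 11
  expect_error(smooth_map(v, bad, 10), "grid")
})

test_that("randomization t-test controls the null and detects shifts", {
  set.seed(80)
  a <- matrix(rnorm(20 * 100), 20)
  st0 <- randomization_ttest(a, a, n_rand = 200)
  expect_equal(sum(st0$sig_mask), 0)

  # known shift at 10 of 500 voxels, n = 20 subjects
  base <- matrix(rnorm(20 * 500, 0, 0.1), 20)
  eff <- base
  eff[, 1:10] <- eff[, 1:10] + 0.2
  st <- randomization_ttest(eff, base, n_rand = 5000)
  expect_gte(sum(st$sig_mask[1:10]), 8)
  expect_lte(sum(st$sig_mask[-(1:10)]), 3)

  expect_error(randomization_ttest(a[1:2, ], a[1:2, ]), "3 subjects")
})

test_that("BH step matches the brute-force oracle", {
  # textbook case
  p <- c(0.001, 0.01, 0.02, 0.5)
  expect_equal(bh_reject_bruteforce(p, 0.05), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(p.adjust(p, "BH") <= 0.05, bh_reject_bruteforce(p, 0.05))

  set.seed(81)
  for (i in 1:100) {
    m <- sample(3:60, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- runif(1, 0.01, 0.2)
    expect_identical(unname(p.adjust(p, "BH") <= q),
                     bh_reject_bruteforce(p, q))
  }
})

test_that("randomization p-values converge to the analytic paired t", {
  set.seed(82)
  d <- matrix(rnorm(20 * 100), 20)
  st <- randomization_ttest(d, matrix(0, 20, 100), n_rand = 2000)
  p_analytic <- apply(d, 2, function(x) t.test(x)$p.value)
  expect_lt(mean(abs(st$p - p_analytic)), 0.02)
  expect_lt(max(abs(st$p - p_analytic)), 0.06)
})

test_that("ROI profiles find the frequency carrying a condition effect", {
  set.seed(83)
  n_subj <- 15; n_vox <- 30
  roi <- roi_spec("visual", 4:9)
  base <- array(rnorm(n_subj * n_vox * 7, 0.1, 0.03),
                c(n_subj, n_vox, 7))
  eff <- base
  n_roi <- length(roi$voxel_indices)
  eff[, roi$voxel_indices, 4] <- eff[, roi$voxel_indices, 4] +
    rnorm(n_subj * n_roi, 0.05, 0.01)
  prof <- roi_frequency_profile(eff, base, roi, freqs = 1:7)
  expect_equal(prof$freq[which.max(abs(prof$t))], 4)
  expect_true(prof$sig_corrected[4])

  # equal-distribution conditions: mostly quiet
  null_b <- array(rnorm(n_subj * n_vox * 7, 0.1, 0.03),
                  c(n_subj, n_vox, 7))
  prof0 <- roi_frequency_profile(base, null_b, roi, freqs = 1:7)
  expect_lt(mean(prof0$sig_uncorrected), 0.5)

  # single-voxel ROI reduces to that voxel's paired t
  r1 <- roi_spec("one", 5L)
  prof1 <- roi_frequency_profile(eff, base, r1, freqs = 1:7)
  tt <- t.test(eff[, 5, 4], base[, 5, 4], paired = TRUE)
  expect_equal(prof1$t[4], unname(tt$statistic))

  expect_error(roi_spec("none", integer(0)), "non-empty")
})

test_that("regression Z-contrast localizes a behavior-linked voxel", {
  set.seed(84)
  n <- 44; n_vox <- 50
  acc1 <- gen_behavior(rnorm(n, 0.5, 0.1), 45, 10, seed = 85)
  acc2 <- gen_behavior(rnorm(n, 0.5, 0.1), 45, 10, seed = 86)
  m1 <- matrix(rnorm(n * n_vox, 0.2, 0.04), n)
  m2 <- matrix(rnorm(n * n_vox, 0.2, 0.04), n)
  m1[, 17] <- 0.2 + 0.004 * (acc1 - mean(acc1)) + rnorm(n, 0, 0.01)
  z <- regression_z_contrast(m1, m2, acc1, acc2)
  expect_equal(which.max(z$statistic), 17L)
  expect_true(z$sig_mask[17])

  zid <- regression_z_contrast(m1, m1, acc1, acc1)
  expect_true(all(abs(zid$statistic) < 1e-12))

  expect_error(regression_z_contrast(m1, m2, rep(80, n), acc2), "variance")
})

test_that("Z-contrast null calibration matches its construction", {
  set.seed(87)
  n <- 30; n_vox <- 40; reps <- 40
  hits <- 0; total <- 0
  for (r in seq_len(reps)) {
    acc <- sample(gen_behavior(rnorm(n, 0.5, 0.1), 45, 10, seed = 880 + r))
    m1 <- matrix(rnorm(n * n_vox, 0.2, 0.04), n)
    m2 <- matrix(rnorm(n * n_vox, 0.2, 0.04), n)
    z <- regression_z_contrast(m1, m2, acc, sample(acc))
    hits <- hits + sum(z$sig_mask)
    total <- total + n_vox
  }
  # Z1 - Z2 is N(0, 2) under the null, so the two-sided 0.005 threshold
  # on a unit-normal scale is exceeded at ~ 2*(1-pnorm(thr/sqrt(2)))
  expected <- 2 * (1 - pnorm(qnorm(1 - 0.005 / 2) / sqrt(2)))
  expect_lt(abs(hits / total - expected),
            3 * sqrt(expected * (1 - expected) / total) + 0.01)
})

test_that("behavior correlation and median split behave as specified", {
  co <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  acc <- c(10, 20, 30, 40, 50, 60)
  fc <- fisher_z_correlation(co, acc)
  expect_equal(fc$spearman_r, 1)
  expect_equal(fc$pearson_r, cor(atanh(sqrt(co)), acc))

  expect_warning(fc0 <- fisher_z_correlation(rep(0.3, 6), acc), "constant")
  expect_true(is.na(fc0$pearson_r))

  ms <- median_split_test(rnorm(6, 1), c(70, 80, 90, 90, 100, 100))
  expect_equal(ms$n_good, 4)
  expect_equal(ms$n_poor, 2)
  expect_equal(ms$median, 90)

  set.seed(88)
  null_p <- replicate(30, {
    median_split_test(rnorm(20, 0.5, 0.1),
                      gen_behavior(rnorm(20, 0.5, 0.1), 0, 15,
                                   seed = sample.int(1e6, 1)))$p
  })
  expect_gt(mean(null_p > 0.05), 0.7)

  expect_error(median_split_test(rnorm(6), rep(90, 6)), "equal")
})

test_that("behavior tables round-trip as delimited text", {
  dir <- withr::local_tempdir()
  b <- data.frame(subject = 1:4, condition = "av_congruent",
                  accuracy = c(70, 80, 90, 100))
  write_behavior(b, file.path(dir, "b.tsv"))
  expect_equal(read_behavior(file.path(dir, "b.tsv")), b)
})
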