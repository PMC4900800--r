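#' Region-of-interest specification
#'
#' @param name label for the region.
#' @param voxel_indices integer voxel indices (non-empty, >= 1).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(name, voxel_indices) {
  voxel_indices <- as.integer(voxel_indices)
  if (length(voxel_indices) == 0L || any(voxel_indices < 1L))
    stop("voxel_indices must be a non-empty set of positive indices",
         call. = FALSE)
  structure(list(name = name, voxel_indices = voxel_indices),
            class = "roi_spec")
}

.new_stat_map <- function(statistic, p, sig_mask, df, correction, threshold,
                          extra = list()) {
  structure(c(list(statistic = statistic, p = p, sig_mask = sig_mask,
                   df = df, correction = correction, threshold = threshold),
              extra),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d voxels, df=%g, %s at %g: %d significant\n",
              length(x$statistic), x$df, x$correction, x$threshold,
              sum(x$sig_mask, na.rm = TRUE)))
  invisible(x)
}

#' Fisher z-transform for coherence values
#'
#' Coherence is a squared-correlation analogue, so the default
#' variance-stabilizing transform is `atanh(sqrt(C))`; `"atanh"` applies
#' the plain arc-tanh for values already on a correlation scale.
#'
#' @param C coherence values in `[0, 1]`.
#' @param transform `"atanh_sqrt"` (default) or `"atanh"`.
#' @return transformed values.
#' @export
fisher_z_coh <- function(C, transform = c("atanh_sqrt", "atanh")) {
  transform <- match.arg(transform)
  C <- pmin(pmax(C, 0), 1 - 1e-12)
  if (transform == "atanh_sqrt") atanh(sqrt(C)) else atanh(C)
}

#' Gaussian smoothing of a volumetric map on a regular grid
#'
#' Separable Gaussian smoothing with the stated full width at half
#' maximum (default 10 mm), using reflective boundaries. Constant maps
#' are unchanged; `fwhm_mm = 0` is the identity.
#'
#' @param values numeric vector, one value per voxel.
#' @param voxel_coords voxels x 3 coordinate matrix on a regular grid
#'   (as in [leadfield_model()]).
#' @param fwhm_mm kernel FWHM in mm.
#' @return smoothed values in the same voxel order.
#' @export
smooth_map <- function(values, voxel_coords, fwhm_mm = 10) {
  voxel_coords <- as.matrix(voxel_coords)
  if (length(values) != nrow(voxel_coords))
    stop("values and voxel_coords disagree in length", call. = FALSE)
  if (fwhm_mm == 0) return(values)
  ax <- lapply(1:3, function(d) sort(unique(voxel_coords[, d])))
  dims <- vapply(ax, length, integer(1L))
  if (prod(dims) != length(values))
    stop("voxel coordinates do not form a full regular grid", call. = FALSE)
  spacing <- vapply(ax, function(u) if (length(u) > 1L) {
    du <- diff(u)
    if (max(du) - min(du) > 1e-8 * max(du))
      stop("irregular grid spacing", call. = FALSE)
    du[1L]
  } else 1, numeric(1L))
  idx <- vapply(1:3, function(d) match(voxel_coords[, d], ax[[d]]),
                integer(length(values)))
  arr <- array(NA_real_, dims)
  arr[cbind(idx)] <- values
  if (anyNA(arr))
    stop("voxel coordinates do not form a full regular grid", call. = FALSE)
  for (d in 1:3) {
    if (dims[d] == 1L) next
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing[d]
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r):r)^2 / (2 * sigma^2))
    k <- k / sum(k)
    arr <- .conv_reflect(arr, k, d)
  }
  arr[cbind(idx)]
}

# reflective-boundary convolution of a 3-D array along dimension d
.conv_reflect <- function(arr, k, d) {
  dims <- dim(arr)
  perm <- c(d, setdiff(1:3, d))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = dims[d])
  n <- nrow(m)
  r <- (length(k) - 1L) / 2L
  # reflect indices (i<1 -> 2-i ; i>n -> 2n-i), iterated so kernels wider
  # than the axis stay in range
  ii <- seq(1L - r, n + r)
  while (any(ii < 1L | ii > n)) {
    ii[ii < 1L] <- 2L - ii[ii < 1L]
    ii[ii > n] <- 2L * n - ii[ii > n]
  }
  mp <- m[ii, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
  a2 <- array(out, dims[perm])
  aperm(a2, order(perm))
}

#' Dependent-samples randomization t-test with FDR correction
#'
#' Voxel-wise paired t statistics between two sets of subject maps. The
#' null distribution is estimated by Monte-Carlo random sign flips of
#' the paired differences (default 500 randomizations); the per-voxel
#' p-value is the rank of the observed `|t|` within its null, and
#' multiple-comparison correction uses Benjamini-Hochberg FDR at `q`.
#' Reproducible under a fixed RNG seed set by the caller.
#'
#' @param maps_a,maps_b numeric matrices, subjects x voxels, paired by
#'   row (subject).
#' @param n_rand number of sign-flip randomizations (default 500).
#' @param q FDR level (default 0.05).
#' @return a `stat_map` with elements `statistic` (t), `p`
#'   (randomization p), `p_adj` (BH-adjusted), `sig_mask`, `df`.
#' @export
randomization_ttest <- function(maps_a, maps_b, n_rand = 500L, q = 0.05) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (!identical(dim(maps_a), dim(maps_b)))
    stop("map sets must have identical dimensions", call. = FALSE)
  n <- nrow(maps_a)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  D <- maps_a - maps_b
  ss <- colSums(D^2)
  mobs <- colMeans(D)
  vobs <- (ss - n * mobs^2) / (n - 1L)
  t_obs <- mobs / sqrt(pmax(vobs, .Machine$double.eps) / n)
  signs <- matrix(sample(c(-1, 1), n_rand * n, replace = TRUE), n_rand, n)
  M <- signs %*% D / n
  # sign flips leave the per-voxel sum of squares unchanged
  Vn <- sweep(-n * M^2, 2L, ss, "+") / (n - 1L)
  Tn <- M / sqrt(pmax(Vn, .Machine$double.eps) / n)
  exceed <- colSums(abs(Tn) >= matrix(abs(t_obs), n_rand, ncol(D),
                                      byrow = TRUE))
  p <- (1 + exceed) / (n_rand + 1)
  p_adj <- p.adjust(p, method = "BH")
  .new_stat_map(t_obs, p, p_adj <= q, df = n - 1L, correction = "fdr",
                threshold = q, extra = list(p_adj = p_adj, n_rand = n_rand))
}

#' ROI-averaged frequency profile of a paired contrast
#'
#' Averages map values within a region of interest per subject and
#' frequency, then runs a paired t-test at each frequency. Reports both
#' the uncorrected p-value and a Bonferroni-corrected significance flag
#' over the tested frequencies, mirroring the two significance lines of
#' an ROI frequency-profile plot.
#'
#' @param maps_a,maps_b numeric arrays, subjects x voxels x frequencies.
#' @param roi a [roi_spec()].
#' @param freqs frequency labels in Hz (default `1:dim\[3\]`).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `freq`, `t`, `df`, `p`,
#'   `sig_uncorrected`, `sig_corrected`.
#' @export
roi_frequency_profile <- function(maps_a, maps_b, roi, freqs = NULL,
                                  alpha = 0.05) {
  stopifnot(inherits(roi, "roi_spec"))
  da <- dim(maps_a)
  if (!identical(da, dim(maps_b)) || length(da) != 3L)
    stop("maps must be subjects x voxels x frequencies arrays", call. = FALSE)
  if (max(roi$voxel_indices) > da[2L])
    stop("ROI indices out of range", call. = FALSE)
  if (is.null(freqs)) freqs <- seq_len(da[3L])
  n_f <- length(freqs)
  res <- lapply(seq_len(n_f), function(j) {
    ra <- rowMeans(maps_a[, roi$voxel_indices, j, drop = FALSE], dims = 1L)
    rb <- rowMeans(maps_b[, roi$voxel_indices, j, drop = FALSE], dims = 1L)
    if (sd(ra - rb) < .Machine$double.eps^0.5 * (sd(ra) + 1e-300)) {
      # degenerate contrast (identical maps): no evidence either way
      return(data.frame(freq = freqs[j], t = 0,
                        df = length(ra) - 1L, p = 1))
    }
    tt <- t.test(ra, rb, paired = TRUE)
    data.frame(freq = freqs[j], t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$sig_uncorrected <- out$p < alpha
  out$sig_corrected <- out$p < alpha / n_f
  out
}

# vectorized per-voxel simple regression of map values on a covariate:
# returns the t statistic of the slope at each voxel
.regression_t <- function(maps, x) {
  n <- nrow(maps)
  if (sd(x) == 0) stop("zero-variance accuracy", call. = FALSE)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- sweep(maps, 2L, colMeans(maps))
  beta <- as.numeric(crossprod(xc, yc)) / sxx
  fit <- outer(xc, beta)
  rss <- colSums((yc - fit)^2)
  df <- n - 2L
  se <- sqrt(pmax(rss / df, .Machine$double.eps) / sxx)
  list(t = beta / se, df = df)
}

#' Z-difference map of across-subject accuracy regressions
#'
#' For each condition, regresses the voxel-wise coherence values on
#' comprehension accuracy across subjects, converts the slope t-value at
#' each voxel to a standard Z-value through the inverse-normal transform
#' of the t CDF, and subtracts the two Z-maps. The result highlights
#' voxels where entrainment predicts accuracy more strongly in the first
#' condition than in the second.
#'
#' @param maps_cond1,maps_cond2 numeric matrices, subjects x voxels
#'   (same subjects in both conditions).
#' @param accuracy_cond1,accuracy_cond2 per-subject accuracies.
#' @param p_thresh two-sided threshold on the Z-difference (default
#'   0.005).
#' @return a `stat_map` whose `statistic` is `Z1 - Z2`, with `sig_mask`
#'   at `|Z1 - Z2| > qnorm(1 - p_thresh / 2)` and elements `z1`, `z2`.
#' @export
regression_z_contrast <- function(maps_cond1, maps_cond2,
                                  accuracy_cond1, accuracy_cond2,
                                  p_thresh = 0.005) {
  maps_cond1 <- as.matrix(maps_cond1); maps_cond2 <- as.matrix(maps_cond2)
  if (!identical(dim(maps_cond1), dim(maps_cond2)))
    stop("condition maps must have identical dimensions", call. = FALSE)
  if (nrow(maps_cond1) != length(accuracy_cond1) ||
      nrow(maps_cond2) != length(accuracy_cond2))
    stop("accuracy length must equal subject count", call. = FALSE)
  r1 <- .regression_t(maps_cond1, accuracy_cond1)
  r2 <- .regression_t(maps_cond2, accuracy_cond2)
  to_z <- function(t, df) {
    pr <- pt(t, df)
    qnorm(pmin(pmax(pr, 1e-15), 1 - 1e-15))
  }
  z1 <- to_z(r1$t, r1$df); z2 <- to_z(r2$t, r2$df)
  zd <- z1 - z2
  thr <- qnorm(1 - p_thresh / 2)
  .new_stat_map(zd, p = 2 * pnorm(-abs(zd)), sig_mask = abs(zd) > thr,
                df = r1$df, correction = "uncorrected", threshold = p_thresh,
                extra = list(z1 = z1, z2 = z2))
}

#' Correlation between coherence and comprehension accuracy
#'
#' Pearson correlation on Fisher z-transformed coherence values (the
#' default transform for a squared-correlation quantity is
#' `atanh(sqrt(C))`) plus the Spearman rank correlation on the raw
#' values, with two-sided p-values.
#'
#' @param coh per-subject coherence values (n >= 5).
#' @param accuracy per-subject accuracies.
#' @param transform passed to [fisher_z_coh()].
#' @return list with `pearson_r`, `pearson_p`, `spearman_r`,
#'   `spearman_p`, `n`. Constant inputs yield `NA` with a warning.
#' @export
fisher_z_correlation <- function(coh, accuracy,
                                 transform = c("atanh_sqrt", "atanh")) {
  if (length(coh) != length(accuracy) || length(coh) < 5L)
    stop("need matched vectors with n >= 5", call. = FALSE)
  if (sd(coh) == 0 || sd(accuracy) == 0) {
    warning("constant input: correlation undefined", call. = FALSE)
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_r = NA_real_, spearman_p = NA_real_,
                n = length(coh)))
  }
  z <- fisher_z_coh(coh, transform)
  pe <- cor.test(z, accuracy)
  sp <- cor.test(coh, accuracy, method = "spearman", exact = FALSE)
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_r = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(coh))
}

#' Median-split comparison of coherence between performance groups
#'
#' Splits subjects at the median accuracy (subjects exactly at the
#' median join the good-performer group) and compares Fisher
#' z-transformed coherence between the groups with a two-sample t-test
#' (pooled variance by default).
#'
#' @param coh per-subject coherence values (n >= 6).
#' @param accuracy per-subject accuracies; must not be all equal.
#' @param var_equal pooled (`TRUE`, default) or Welch t-test.
#' @param transform passed to [fisher_z_coh()].
#' @return list with `t`, `df`, `p`, `n_good`, `n_poor`, `median`.
#' @export
median_split_test <- function(coh, accuracy, var_equal = TRUE,
                              transform = c("atanh_sqrt", "atanh")) {
  if (length(coh) != length(accuracy) || length(coh) < 6L)
    stop("need matched vectors with n >= 6", call. = FALSE)
  if (length(unique(accuracy)) == 1L)
    stop("all accuracies equal: no split possible", call. = FALSE)
  med <- median(accuracy)
  good <- accuracy >= med
  z <- fisher_z_coh(coh, transform)
  tt <- t.test(z[good], z[!good], var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       n_good = sum(good), n_poor = sum(!good), median = med)
}

#' Write / read a behavior table as delimited text
#'
#' Tab-separated columns `subject`, `condition`, `accuracy`.
#'
#' @param behavior data.frame with those columns.
#' @param path file path.
#' @return `read_behavior` returns the data.frame.
#' @export
write_behavior <- function(behavior, path) {
  stopifnot(all(c("subject", "condition", "accuracy") %in% names(behavior)))
  write.table(behavior, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) read.delim(path)
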