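#' Run the entrainment mapping stage over a whole study
#'
#' For every subject, condition and analysis frequency: computes the
#' sensor cross-spectral density, builds DICS spatial filters, applies
#' them to band-pass filtered sensor data (center +/- `halfwidth` Hz),
#' and evaluates voxel-wise coherence with the lip driver, partial
#' coherence conditioning out the condition's acoustic envelope, and the
#' corresponding surrogate variants computed against the time-shifted
#' lip driver.
#'
#' @param study a [gen_synthetic_study()] (or [read_study()]) bundle.
#' @param freqs analysis frequencies in Hz (default 1:7).
#' @param spec a [segment_spec()].
#' @param halfwidth band half-width in Hz (default 3).
#' @param shift_s surrogate shift in seconds (default 30).
#' @param reg_frac beamformer regularization fraction (default 0.05).
#' @param kinds subset of `c("coherence", "partial_coherence",
#'   "surrogate", "surrogate_partial")`.
#' @param verbose print per-subject progress to stderr.
#' @return an object of class `entrainment_maps`: list with `maps`
#'   (`[[condition]][[kind]]` = subjects x voxels x frequencies arrays),
#'   `freqs`, `params`, and a deterministic `manifest` (parameters plus
#'   MD5 hashes of the inputs).
#' @export
run_entrainment <- function(study, freqs = 1:7, spec = segment_spec(),
                            halfwidth = 3, shift_s = 30, reg_frac = 0.05,
                            kinds = c("coherence", "partial_coherence",
                                      "surrogate", "surrogate_partial"),
                            verbose = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  kinds <- match.arg(kinds, several.ok = TRUE)
  for (comp in c("lip", "sensor_data", "leadfield", "audio_env", "behavior"))
    if (is.null(study[[comp]]))
      stop("study bundle is missing component '", comp, "'", call. = FALSE)
  fs <- study$config$fs
  conds <- names(study$sensor_data)
  nv <- study$leadfield$n_voxels
  n_subj <- length(study$sensor_data[[1L]])
  lip_sur <- surrogate_driver(study$lip, shift_s)
  maps <- lapply(conds, function(cn) {
    arrs <- lapply(kinds, function(k) array(NA_real_,
                                            c(n_subj, nv, length(freqs))))
    names(arrs) <- kinds
    arrs
  })
  names(maps) <- conds
  need_partial <- any(c("partial_coherence", "surrogate_partial") %in% kinds)
  for (ci in seq_along(conds)) {
    cn <- conds[ci]
    for (si in seq_len(n_subj)) {
      if (verbose)
        message(sprintf("condition %s subject %d/%d", cn, si, n_subj))
      X <- study$sensor_data[[cn]][[si]]
      for (fi in seq_along(freqs)) {
        f <- freqs[fi]
        csd <- sensor_csd(X, fs, f, spec)
        flt <- dics_filters(csd, study$leadfield, reg_frac)
        Xb <- t(apply(X, 1L, bandpass, fs = fs, center = f,
                      halfwidth = halfwidth))
        src <- reconstruct_sources(Xb, flt)
        vcoefs <- t(apply(src, 1L, .seg_coef_bin, fs = fs, freq = f,
                          spec = spec))
        lipc <- .seg_coef_bin(bandpass(study$lip$values, fs, f, halfwidth),
                              fs, f, spec)
        surc <- .seg_coef_bin(bandpass(lip_sur$values, fs, f, halfwidth),
                              fs, f, spec)
        audc <- if (need_partial)
          .seg_coef_bin(bandpass(study$audio_env[[cn]]$values, fs, f,
                                 halfwidth), fs, f, spec)
        for (v in seq_len(nv)) {
          if ("coherence" %in% kinds)
            maps[[cn]][["coherence"]][si, v, fi] <-
              .coh_from_coefs(vcoefs[v, ], lipc)
          if ("partial_coherence" %in% kinds)
            maps[[cn]][["partial_coherence"]][si, v, fi] <-
              .coh_from_coefs(vcoefs[v, ], lipc, audc)
          if ("surrogate" %in% kinds)
            maps[[cn]][["surrogate"]][si, v, fi] <-
              .coh_from_coefs(vcoefs[v, ], surc)
          if ("surrogate_partial" %in% kinds)
            maps[[cn]][["surrogate_partial"]][si, v, fi] <-
              .coh_from_coefs(vcoefs[v, ], surc, audc)
        }
      }
    }
  }
  params <- list(freqs = freqs, win_s = spec$win_s, step_s = spec$step_s,
                 taper = spec$taper, halfwidth = halfwidth,
                 shift_s = shift_s, reg_frac = reg_frac, kinds = kinds)
  manifest <- list(
    package = "avcoh",
    version = as.character(utils::packageVersion("avcoh")),
    params = params,
    config = unclass(study$config),
    input_hash = .obj_md5(study$sensor_data),
    driver_hash = .obj_md5(study$lip$values),
    map_hash = .obj_md5(maps))
  structure(list(maps = maps, freqs = freqs, params = params,
                 manifest = manifest),
            class = "entrainment_maps")
}

.obj_md5 <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(obj, con, version = 2L)
  close(con)
  unname(md5sum(tf))
}

#' @export
print.entrainment_maps <- function(x, ...) {
  d <- dim(x$maps[[1L]][[1L]])
  cat(sprintf(
    "<entrainment_maps> %d conditions x {%s}; %d subjects, %d voxels, freqs %s Hz\n",
    length(x$maps), paste(names(x$maps[[1L]]), collapse = ", "),
    d[1L], d[2L], paste(range(x$freqs), collapse = "-")))
  invisible(x)
}

#' Group-level figure analyses on entrainment maps
#'
#' Reproduces the group-analysis logic of an attention-modulated
#' entrainment study on the maps from [run_entrainment()]:
#' condition-versus-surrogate and condition-versus-condition
#' randomization t-maps at the frequency of interest, ROI frequency
#' profiles of the attended contrast, and the behavioral linkage
#' analyses (across-subject regression Z-difference map between the
#' high- and low-attention conditions, correlation of peak-voxel
#' partial coherence with accuracy, and a median-split group test).
#' Maps are Gaussian-smoothed before group statistics.
#'
#' @param ent an [run_entrainment()] result containing the conditions
#'   `all_congruent`, `all_incongruent`, `av_congruent`, `av_incongruent`.
#' @param study the study bundle the maps came from (for coordinates and
#'   behavior).
#' @param roi a [roi_spec()] for the frequency profile; defaults to the
#'   study's lip-coupled voxels.
#' @param freq_hz frequency of interest in Hz (default 4).
#' @param n_rand,q randomization count and FDR level.
#' @param fwhm_mm smoothing kernel FWHM (default 10).
#' @param p_thresh two-sided threshold for the Z-difference map.
#' @param seed optional RNG seed for the randomization tests.
#' @param out_dir optional directory; when given, result tables are
#'   written there as tab-separated text.
#' @return list with `stat_maps` (named `stat_map` objects),
#'   `roi_profiles` (data.frames), `zdiff` (`stat_map`), `peak_voxel`,
#'   `correlation`, `median_split`.
#' @export
run_figure_analyses <- function(ent, study, roi = NULL, freq_hz = 4,
                                n_rand = 500L, q = 0.05, fwhm_mm = 10,
                                p_thresh = 0.005, seed = NULL,
                                out_dir = NULL) {
  stopifnot(inherits(ent, "entrainment_maps"),
            inherits(study, "synthetic_study"))
  need <- c("all_congruent", "all_incongruent", "av_congruent",
            "av_incongruent")
  missing_c <- setdiff(need, names(ent$maps))
  if (length(missing_c))
    stop("missing condition(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  if (!all(c("partial_coherence", "surrogate_partial") %in%
           names(ent$maps[[1L]])))
    stop("figure analyses need partial_coherence and surrogate_partial maps",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(roi))
    roi <- roi_spec("coupled", study$config$coupled_voxels)
  fi <- match(freq_hz, ent$freqs)
  if (is.na(fi)) stop("freq_hz not among the analysis frequencies",
                      call. = FALSE)
  coords <- study$leadfield$voxel_coords
  smooth_subject_maps <- function(m)
    t(apply(m, 1L, smooth_map, voxel_coords = coords, fwhm_mm = fwhm_mm))
  pc_s <- lapply(need, function(cn)
    smooth_subject_maps(ent$maps[[cn]][["partial_coherence"]][, , fi]))
  names(pc_s) <- need
  sur_s <- smooth_subject_maps(
    ent$maps[["av_congruent"]][["surrogate_partial"]][, , fi])
  stat_maps <- list(
    av_congruent_vs_surrogate =
      randomization_ttest(pc_s[["av_congruent"]], sur_s, n_rand, q),
    av_congruent_vs_all_incongruent =
      randomization_ttest(pc_s[["av_congruent"]], pc_s[["all_incongruent"]],
                          n_rand, q),
    av_congruent_vs_all_congruent =
      randomization_ttest(pc_s[["av_congruent"]], pc_s[["all_congruent"]],
                          n_rand, q))
  roi_profiles <- list(
    av_congruent_vs_surrogate = roi_frequency_profile(
      ent$maps[["av_congruent"]][["partial_coherence"]],
      ent$maps[["av_congruent"]][["surrogate_partial"]],
      roi, freqs = ent$freqs),
    av_congruent_vs_all_congruent = roi_frequency_profile(
      ent$maps[["av_congruent"]][["partial_coherence"]],
      ent$maps[["all_congruent"]][["partial_coherence"]],
      roi, freqs = ent$freqs))
  beh <- study$behavior
  acc_of <- function(cn) {
    b <- beh[beh$condition == cn, ]
    b$accuracy[order(b$subject)]
  }
  zdiff <- regression_z_contrast(pc_s[["av_congruent"]],
                                 pc_s[["av_incongruent"]],
                                 acc_of("av_congruent"),
                                 acc_of("av_incongruent"),
                                 p_thresh = p_thresh)
  peak_voxel <- which.max(zdiff$statistic)
  peak_coh <- ent$maps[["av_congruent"]][["partial_coherence"]][, peak_voxel, fi]
  correlation <- fisher_z_correlation(peak_coh, acc_of("av_congruent"))
  msplit <- median_split_test(peak_coh, acc_of("av_congruent"))
  out <- list(stat_maps = stat_maps, roi_profiles = roi_profiles,
              zdiff = zdiff, peak_voxel = peak_voxel,
              correlation = correlation, median_split = msplit,
              freq_hz = freq_hz)
  if (!is.null(out_dir)) .write_report(out, out_dir)
  out
}

.write_report <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(res$roi_profiles))
    write.table(res$roi_profiles[[nm]],
                file.path(dir, paste0("roi_profile_", nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in names(res$stat_maps)) {
    sm <- res$stat_maps[[nm]]
    write.table(data.frame(voxel = seq_along(sm$statistic), t = sm$statistic,
                           p = sm$p, p_adj = sm$p_adj,
                           significant = sm$sig_mask),
                file.path(dir, paste0("stat_map_", nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.table(data.frame(voxel = seq_along(res$zdiff$statistic),
                         z_diff = res$zdiff$statistic,
                         significant = res$zdiff$sig_mask),
              file.path(dir, "zdiff_map.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  summary_df <- data.frame(
    quantity = c("peak_voxel", "pearson_r", "pearson_p", "spearman_r",
                 "spearman_p", "median_split_t", "median_split_p",
                 "n_good", "n_poor"),
    value = c(res$peak_voxel, res$correlation$pearson_r,
              res$correlation$pearson_p, res$correlation$spearman_r,
              res$correlation$spearman_p, res$median_split$t,
              res$median_split$p, res$median_split$n_good,
              res$median_split$n_poor))
  write.table(summary_df, file.path(dir, "behavior_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
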