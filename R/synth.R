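#' Configuration for a synthetic entrainment study
#'
#' Bundles every parameter of the synthetic multi-subject study: grid and
#' sensor-array sizes, recording duration and rate, which voxels couple
#' to the lip driver, at which frequency and how strongly per condition,
#' the lip-audio coherence of the stimulus, sensor noise, and how
#' comprehension accuracy depends on each subject's coupling strength.
#'
#' Coupling strengths are target magnitude-squared coherences: a coupled
#' voxel's source series is built as
#' `sqrt(C) * shared + sqrt(1 - C) * noise` from a band-limited shared
#' component (the filtered driver) and spectrally matched independent
#' noise, so the population coherence at the coupling frequency equals
#' `C` exactly (`C = SNR / (1 + SNR)`).
#'
#' @param n_subjects,n_voxels,n_sensors counts.
#' @param duration_s recording duration per condition in seconds.
#' @param fs sampling rate in Hz (default 250, the common analysis rate).
#' @param coupled_voxels integer indices of lip-coupled voxels.
#' @param coupling_freq coupling frequency in Hz (default 4, the
#'   syllable-rate band where visual attention effects concentrate).
#' @param coupling_strength named numeric vector of target coherences per
#'   condition, each in `[0, 1]`.
#' @param coupling_bandwidth half-width in Hz of the injected band
#'   (default 1.5).
#' @param coupling_subject_sd between-subject SD of the realized coupling
#'   strength (default 0.1); this is what behavioral accuracy tracks.
#' @param audio_coupled_voxels voxels coupled to the acoustic envelope
#'   instead of the lip driver (default none); useful for validating
#'   partial-coherence cancellation.
#' @param lip_audio_coherence target lip-envelope coherence in the 4-8 Hz
#'   syllable band for congruent conditions (default 0.5).
#' @param noise_sd sensor noise SD (default 1).
#' @param behavior_slope accuracy points per unit coherence (default 45).
#' @param behavior_noise_sd accuracy noise SD in points (default 10).
#' @param behavior_target_mean named mean accuracy in percent per
#'   condition.
#' @param seed integer seed controlling the whole study.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 10L, n_voxels = 96L,
                             n_sensors = 32L, duration_s = 120,
                             fs = 250,
                             coupled_voxels = c(10L, 40L),
                             coupling_freq = 4,
                             coupling_strength = c(all_congruent = 0.30,
                                                   all_incongruent = 0.30,
                                                   av_congruent = 0.50,
                                                   av_incongruent = 0.15),
                             coupling_bandwidth = 1.5,
                             coupling_subject_sd = 0.1,
                             audio_coupled_voxels = integer(0),
                             lip_audio_coherence = 0.5,
                             noise_sd = 1,
                             behavior_slope = 45,
                             behavior_noise_sd = 10,
                             behavior_target_mean = c(all_congruent = 85,
                                                      all_incongruent = 77.7,
                                                      av_congruent = 83.4,
                                                      av_incongruent = 75.7),
                             seed = 1L) {
  if (any(coupling_strength < 0 | coupling_strength > 1))
    stop("coupling strengths must lie in [0, 1]", call. = FALSE)
  if (lip_audio_coherence < 0 || lip_audio_coherence > 1)
    stop("lip_audio_coherence must lie in [0, 1]", call. = FALSE)
  if (!(fs > 2 * coupling_freq))
    stop("need fs > 2 * coupling_freq", call. = FALSE)
  if (length(coupled_voxels) &&
      (min(coupled_voxels) < 1L || max(coupled_voxels) > n_voxels))
    stop("coupled_voxels out of range", call. = FALSE)
  if (length(audio_coupled_voxels) &&
      (min(audio_coupled_voxels) < 1L || max(audio_coupled_voxels) > n_voxels))
    stop("audio_coupled_voxels out of range", call. = FALSE)
  if (is.null(names(coupling_strength)))
    stop("coupling_strength must be named by condition", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_voxels = as.integer(n_voxels),
                 n_sensors = as.integer(n_sensors),
                 duration_s = duration_s, fs = fs,
                 coupled_voxels = as.integer(coupled_voxels),
                 coupling_freq = coupling_freq,
                 coupling_strength = coupling_strength,
                 coupling_bandwidth = coupling_bandwidth,
                 coupling_subject_sd = coupling_subject_sd,
                 audio_coupled_voxels = as.integer(audio_coupled_voxels),
                 lip_audio_coherence = lip_audio_coherence,
                 noise_sd = noise_sd,
                 behavior_slope = behavior_slope,
                 behavior_noise_sd = behavior_noise_sd,
                 behavior_target_mean = behavior_target_mean,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

.circshift <- function(x, k) {
  n <- length(x)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(x)
  c(x[(n - k + 1L):n], x[1:(n - k)])
}

#' Generate a lip-aperture-like driver signal
#'
#' Low-pass filtered (7 Hz cutoff, order-4 zero-phase Butterworth)
#' Gaussian noise with additional narrowband energy at 1-4 Hz, shifted
#' positive and scaled to a plausible aperture-area range. The resulting
#' spectrum is dominated by components below 7 Hz with a peak in the
#' 0-4 Hz range, mimicking the opening-closing dynamics of a speaker's
#' mouth during continuous speech.
#'
#' @param duration_s duration in seconds (>= 60).
#' @param fs sampling rate in Hz (>= 50).
#' @param seed integer seed; the series is deterministic given the seed.
#' @param mean_px2,sd_px2 target mean and SD of the area series in px^2.
#' @return a [stimulus_signal()] of kind `"lip_area"` with nonnegative
#'   values.
#' @export
gen_lip_driver <- function(duration_s, fs, seed, mean_px2 = 4000,
                           sd_px2 = 600) {
  if (duration_s < 60) stop("duration_s must be >= 60", call. = FALSE)
  if (fs < 50) stop("fs must be >= 50", call. = FALSE)
  n <- round(duration_s * fs)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  lp <- butter(4, 7 / (fs / 2), type = "low")
  broad <- as.numeric(filtfilt(lp, rnorm(n)))
  narrow <- bandpass(rnorm(n), fs, center = 2.5, halfwidth = 1.5)
  x <- broad / sd(broad) + 1.8 * narrow / sd(narrow)
  x <- (x - mean(x)) / sd(x) * sd_px2 + mean_px2
  x <- pmax(x, 0)
  stimulus_signal(x, fs, "lip_area")
}

#' Generate an audio envelope coherent with a lip driver
#'
#' Builds an envelope-like series whose coherence with the lip driver
#' inside `band_hz` equals `target_coh` by construction: the in-band
#' shared component (band-pass filtered lip signal) is mixed with
#' spectrally matched independent noise (the band-pass filtered,
#' circularly far-shifted lip signal) at the amplitude ratio
#' `sqrt(C) : sqrt(1 - C)`, so the shared-to-noise power ratio is
#' `C / (1 - C)` at every in-band frequency. Out-of-band content is
#' independent band-stop filtered noise.
#'
#' @param lip a [stimulus_signal()] (the lip driver).
#' @param target_coh target magnitude-squared coherence in `[0, 1]`.
#' @param band_hz numeric length-2 band in Hz (default `c(4, 8)`, the
#'   syllable-rate band).
#' @param seed integer seed.
#' @return a nonnegative [stimulus_signal()] of kind `"audio_envelope"`.
#' @export
gen_coupled_envelope <- function(lip, target_coh, band_hz = c(4, 8), seed) {
  stopifnot(inherits(lip, "stimulus_signal"))
  if (target_coh < 0 || target_coh > 1)
    stop("target_coh must lie in [0, 1]", call. = FALSE)
  fs <- lip$fs
  if (!(band_hz[1L] > 0 && band_hz[2L] < fs / 2 && band_hz[1L] < band_hz[2L]))
    stop("band_hz must lie inside (0, fs/2)", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- length(lip$values)
  bp <- butter(4, band_hz / (fs / 2), type = "pass")
  lc <- lip$values - mean(lip$values)
  shared <- as.numeric(filtfilt(bp, lc))
  shifted <- .circshift(lc, round(n * runif(1, 0.35, 0.45)))
  noise_m <- as.numeric(filtfilt(bp, shifted))
  shared <- shared / sd(shared)
  noise_m <- noise_m / sd(noise_m)
  inband <- if (target_coh == 1) shared
            else if (target_coh == 0) noise_m
            else sqrt(target_coh) * shared + sqrt(1 - target_coh) * noise_m
  # widen the stop band so transition-band leakage does not dilute the
  # in-band coherence at the band edges
  stop_band <- c(max(band_hz[1L] - 2, 0.25), min(band_hz[2L] + 2, 0.45 * fs))
  bs <- butter(4, stop_band / (fs / 2), type = "stop")
  outband <- as.numeric(filtfilt(bs, rnorm(n)))
  env <- inband + 0.5 * outband / sd(outband)
  env <- env - min(env)
  stimulus_signal(env, fs, "audio_envelope")
}

#' Render an area series as binary ellipse mask frames
#'
#' Each frame is a filled ellipse of fixed eccentricity (default 0.8, so
#' the minor/vertical semi-axis is 0.6 of the major/horizontal one)
#' whose pixel area tracks the requested series; the fixed shape makes
#' area and minor axis co-informative, as for natural lip apertures. A
#' deterministic sub-pixel center jitter decorrelates rasterization
#' error across frames.
#'
#' @param area_series [stimulus_signal()] or numeric vector of areas in
#'   px^2, one value per frame (positive).
#' @param frame_rate frame rate in Hz (metadata only).
#' @param image_shape height, width in pixels (default `c(128, 128)`).
#' @param eccentricity ellipse eccentricity (default 0.8).
#' @param seed seed for the sub-pixel jitter.
#' @return height x width x frames logical array with attribute
#'   `frame_rate`.
#' @export
gen_lip_masks <- function(area_series, frame_rate, image_shape = c(128L, 128L),
                          eccentricity = 0.8, seed = 1L) {
  area <- if (inherits(area_series, "stimulus_signal")) area_series$values
          else as.numeric(area_series)
  if (length(area) == 0L) stop("empty area series", call. = FALSE)
  if (any(area <= 0)) stop("areas must be positive", call. = FALSE)
  ratio <- sqrt(1 - eccentricity^2)        # minor/major semi-axis ratio
  a <- sqrt(area / (pi * ratio))           # horizontal semi-axis
  b <- a * ratio                           # vertical semi-axis
  h <- image_shape[1L]; w <- image_shape[2L]
  if (any(2 * a + 2 > w) || any(2 * b + 2 > h))
    stop("ellipse exceeds the image frame; enlarge image_shape", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  jx <- runif(length(area)) - 0.5
  jy <- runif(length(area)) - 0.5
  ys <- matrix(seq_len(h), h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  masks <- array(FALSE, dim = c(h, w, length(area)))
  cx0 <- (w + 1) / 2; cy0 <- (h + 1) / 2
  for (i in seq_along(area)) {
    masks[, , i] <- ((xs - cx0 - jx[i]) / a[i])^2 +
                    ((ys - cy0 - jy[i]) / b[i])^2 <= 1
  }
  attr(masks, "frame_rate") <- frame_rate
  masks
}

#' Generate a synthetic leadfield on a regular grid
#'
#' Random fixed-orientation gain columns (unit norm) over a regular 3-D
#' voxel grid. An abstract stand-in for a template-brain leadfield: it
#' preserves the linear mixing structure the beamformer inverts while
#' making no claim about head geometry.
#'
#' @param n_sensors,n_voxels counts.
#' @param grid_spacing grid spacing in mm (default 8).
#' @param seed integer seed.
#' @return a [leadfield_model()].
#' @export
gen_leadfield <- function(n_sensors, n_voxels, grid_spacing = 8, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  dims <- .grid_dims(n_voxels)
  coords <- as.matrix(expand.grid(x = seq_len(dims[1L]),
                                  y = seq_len(dims[2L]),
                                  z = seq_len(dims[3L]))) * grid_spacing
  L <- matrix(rnorm(n_sensors * n_voxels), n_sensors, n_voxels)
  L <- sweep(L, 2L, sqrt(colSums(L^2)), "/")
  leadfield_model(L, coords, grid_spacing)
}

# balanced factor triple a*b*c = n (falls back to flat grids for primes)
.grid_dims <- function(n) {
  best <- c(n, 1L, 1L)
  for (a in rev(seq_len(floor(n^(1 / 3) + 1e-9)))) {
    if (n %% a != 0L) next
    m <- n %/% a
    for (b in rev(seq_len(floor(sqrt(m) + 1e-9)))) {
      if (m %% b != 0L) next
      cand <- sort(c(a, b, m %/% b), decreasing = TRUE)
      if (max(cand) / max(1L, min(cand)) < max(best) / max(1L, min(best)))
        best <- cand
      break
    }
    break
  }
  as.integer(best)
}

#' Generate one subject's sensor recordings
#'
#' Source series at `config$coupled_voxels` contain a band-limited
#' component phase-locked to the lip driver at `coupling_freq`, mixed
#' with spectrally matched independent noise so the source-level
#' coherence equals `strength`; voxels in `config$audio_coupled_voxels`
#' couple to the acoustic envelope instead; all other voxels are unit
#' variance white noise. Sensor data are the leadfield projection of the
#' sources plus white sensor noise of SD `config$noise_sd`.
#'
#' @param config a [synthetic_config()].
#' @param lip lip driver [stimulus_signal()] of matching duration.
#' @param audio_env acoustic envelope [stimulus_signal()] (required when
#'   `config$audio_coupled_voxels` is non-empty).
#' @param leadfield a [leadfield_model()] matching `config`.
#' @param subject_seed integer seed for this subject's noise.
#' @param condition condition name (defaults to the first named coupling
#'   strength).
#' @param strength override of the target coherence for this subject
#'   (defaults to the condition's configured strength).
#' @return sensors x samples numeric matrix with attribute `"truth"`
#'   (list: `condition`, `voxels`, `freq`, `strength`).
#' @export
gen_subject_sensors <- function(config, lip, audio_env = NULL, leadfield,
                                subject_seed, condition = NULL,
                                strength = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(lip, "stimulus_signal"),
            inherits(leadfield, "leadfield_model"))
  if (leadfield$n_sensors != config$n_sensors ||
      leadfield$n_voxels != config$n_voxels)
    stop("leadfield dimensions do not match config", call. = FALSE)
  fs <- config$fs
  n <- round(config$duration_s * fs)
  if (length(lip$values) != n)
    stop("lip driver duration does not match config", call. = FALSE)
  if (is.null(condition)) condition <- names(config$coupling_strength)[1L]
  if (is.null(strength)) strength <- config$coupling_strength[[condition]]
  if (length(config$audio_coupled_voxels) && is.null(audio_env))
    stop("audio_env required for audio-coupled voxels", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(subject_seed))
  sources <- matrix(rnorm(config$n_voxels * n), config$n_voxels, n)
  bf <- .design_band(fs, config$coupling_freq, config$coupling_bandwidth)
  lo <- config$coupling_freq - config$coupling_bandwidth
  hi <- config$coupling_freq + config$coupling_bandwidth
  bstop <- butter(4, c(max(lo - 1, 0.25), min(hi + 1, 0.45 * fs)) / (fs / 2),
                  type = "stop")
  inject <- function(voxels, driver, C) {
    if (length(voxels) == 0L || C <= 0) return()
    dc <- driver$values - mean(driver$values)
    shared <- as.numeric(filtfilt(bf, dc))
    shared <- shared / sd(shared)
    # analytic signal allows a per-voxel carrier phase offset: magnitude
    # coherence with the driver is unaffected, but distinct phases keep
    # simultaneously coupled sources orthogonal in the real-part CSD so
    # the minimum-variance beamformer does not cancel them against each
    # other
    sh_an <- .analytic_signal(shared)
    for (j in seq_along(voxels)) {
      v <- voxels[j]
      phi <- (j - 1L) * pi / max(1L, length(voxels))
      sh_v <- Re(exp(1i * phi) * sh_an)
      sh_v <- sh_v / sd(sh_v)
      shifted <- .circshift(dc, round(n * runif(1, 0.55, 0.8)))
      noise_m <- as.numeric(filtfilt(bf, shifted))
      noise_m <- noise_m / sd(noise_m)
      inband <- sqrt(C) * sh_v + sqrt(1 - C) * noise_m
      bg <- as.numeric(filtfilt(bstop, rnorm(n)))
      sources[v, ] <<- inband + bg / sd(bg)
    }
  }
  inject(config$coupled_voxels, lip, strength)
  inject(config$audio_coupled_voxels, audio_env, strength)
  L <- leadfield$L
  if (length(dim(L)) == 3L)
    stop("free-orientation leadfields are not supported for generation",
         call. = FALSE)
  sensors <- L %*% sources +
    config$noise_sd * matrix(rnorm(config$n_sensors * n),
                             config$n_sensors, n)
  attr(sensors, "truth") <- list(condition = condition,
                                 voxels = config$coupled_voxels,
                                 freq = config$coupling_freq,
                                 strength = strength)
  sensors
}

#' Generate comprehension-accuracy scores from coupling strengths
#'
#' `accuracy = base + slope * coupling + Gaussian noise`, clipped to
#' `[0, 100]` and discretized to steps of 10 to mimic scoring out of 10
#' comprehension questions.
#'
#' @param coupling numeric vector of per-subject coupling strengths.
#' @param slope accuracy points per unit coherence (finite).
#' @param noise_sd accuracy noise SD in points.
#' @param seed integer seed.
#' @param base baseline accuracy in points (default 60).
#' @return numeric vector of accuracies, multiples of 10 in `[0, 100]`.
#' @export
gen_behavior <- function(coupling, slope, noise_sd, seed, base = 60) {
  if (!is.finite(slope)) stop("slope must be finite", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  acc <- base + slope * coupling + rnorm(length(coupling), 0, noise_sd)
  acc <- pmin(pmax(acc, 0), 100)
  round(acc / 10) * 10
}

#' Generate a complete synthetic multi-subject study
#'
#' Produces the full bundle consumed by the analysis pipeline: one lip
#' driver shared by all subjects (the stimulus), per-condition acoustic
#' envelopes (coherent with the lip signal in congruent conditions,
#' independent in incongruent ones), per-subject per-condition sensor
#' recordings through a common synthetic leadfield, comprehension
#' accuracies tied to each subject's realized coupling strength, and a
#' ground-truth table for recovery tests. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_study`: list with `lip`,
#'   `audio_env` (per condition), `sensor_data` (`[[condition]][[subject]]`
#'   matrices), `leadfield`, `behavior` (data.frame `subject`,
#'   `condition`, `accuracy`), `truth` (data.frame) and `config`.
#' @export
gen_synthetic_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  conds <- names(config$coupling_strength)
  s0 <- config$seed %% 100000L
  lip <- gen_lip_driver(config$duration_s, config$fs, seed = s0)
  audio_env <- lapply(seq_along(conds), function(ci) {
    target <- if (grepl("incongruent", conds[ci])) 0
              else config$lip_audio_coherence
    gen_coupled_envelope(lip, target, c(4, 8), seed = s0 * 100L + ci)
  })
  names(audio_env) <- conds
  leadfield <- gen_leadfield(config$n_sensors, config$n_voxels,
                             seed = s0 + 7L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(s0 + 13L)
  strengths <- sapply(conds, function(cn) {
    pmin(pmax(rnorm(config$n_subjects, config$coupling_strength[[cn]],
                    config$coupling_subject_sd), 0.02), 0.95)
  })
  strengths <- matrix(strengths, ncol = length(conds),
                      dimnames = list(NULL, conds))
  sensor_data <- lapply(seq_along(conds), function(ci) {
    lapply(seq_len(config$n_subjects), function(si) {
      gen_subject_sensors(config, lip, audio_env[[ci]], leadfield,
                          subject_seed = s0 * 10000L + ci * 500L + si,
                          condition = conds[ci],
                          strength = strengths[si, ci])
    })
  })
  names(sensor_data) <- conds
  behavior <- do.call(rbind, lapply(seq_along(conds), function(ci) {
    tm <- config$behavior_target_mean[[conds[ci]]]
    base <- tm - config$behavior_slope * config$coupling_strength[[conds[ci]]]
    data.frame(subject = seq_len(config$n_subjects),
               condition = conds[ci],
               accuracy = gen_behavior(strengths[, ci],
                                       config$behavior_slope,
                                       config$behavior_noise_sd,
                                       seed = s0 * 100L + 31L + ci,
                                       base = base))
  }))
  truth <- do.call(rbind, lapply(seq_along(conds), function(ci) {
    if (length(config$coupled_voxels) == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(config$n_subjects), function(si) {
      data.frame(subject = si, condition = conds[ci],
                 voxel = unname(config$coupled_voxels),
                 freq = config$coupling_freq,
                 strength = unname(strengths[si, ci]), row.names = NULL)
    }))
  }))
  structure(list(lip = lip, audio_env = audio_env,
                 sensor_data = sensor_data, leadfield = leadfield,
                 behavior = behavior, truth = truth, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_study> %d subjects, %d conditions, %d voxels, %d sensors, %.0f s @ %g Hz\n",
    cfg$n_subjects, length(cfg$coupling_strength), cfg$n_voxels,
    cfg$n_sensors, cfg$duration_s, cfg$fs))
  invisible(x)
}

#' Write / read a synthetic study bundle
#'
#' The bundle is a directory with a JSON manifest (configuration and
#' dimensions), delimited-text behavior and truth tables, and RDS arrays
#' for the signals, sensors and leadfield.
#'
#' @param study a [gen_synthetic_study()] result.
#' @param dir directory path.
#' @return `read_study` returns a `synthetic_study`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- unclass(study$config)
  # named vectors must serialize as JSON objects even at length one
  cfg$coupling_strength <- as.list(cfg$coupling_strength)
  cfg$behavior_target_mean <- as.list(cfg$behavior_target_mean)
  write_json(cfg, file.path(dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA)
  write.table(study$behavior, file.path(dir, "behavior.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(study$truth))
    write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  saveRDS(study$lip, file.path(dir, "lip.rds"))
  saveRDS(study$audio_env, file.path(dir, "audio_env.rds"))
  saveRDS(study$sensor_data, file.path(dir, "sensor_data.rds"))
  write_leadfield(study$leadfield, file.path(dir, "leadfield"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  cfg <- read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  cfg$coupling_strength <- unlist(cfg$coupling_strength)
  cfg$behavior_target_mean <- unlist(cfg$behavior_target_mean)
  config <- do.call(synthetic_config, cfg)
  behavior <- read.delim(file.path(dir, "behavior.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read.delim(truth_path) else NULL
  structure(list(lip = readRDS(file.path(dir, "lip.rds")),
                 audio_env = readRDS(file.path(dir, "audio_env.rds")),
                 sensor_data = readRDS(file.path(dir, "sensor_data.rds")),
                 leadfield = read_leadfield(file.path(dir, "leadfield")),
                 behavior = behavior, truth = truth, config = config),
            class = "synthetic_study")
}

# preserve the caller's RNG state across seeded generators
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
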