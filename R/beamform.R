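#' Construct a leadfield model
#'
#' Linear forward mapping from source activity at grid voxels to sensor
#' measurements. Fixed-orientation leadfields are sensors x voxels
#' matrices; free-orientation leadfields are sensors x voxels x 3 arrays
#' and are collapsed to the dominant orientation inside [dics_filters()].
#'
#' @param L numeric matrix (sensors x voxels) or array (sensors x voxels
#'   x 3); no column may be all zero.
#' @param voxel_coords voxels x 3 matrix of grid coordinates in mm.
#' @param grid_spacing grid spacing in mm (analysis analogue of an 8-mm
#'   template grid).
#' @return an object of class `leadfield_model`.
#' @export
leadfield_model <- function(L, voxel_coords, grid_spacing = 8) {
  voxel_coords <- as.matrix(voxel_coords)
  nv <- if (length(dim(L)) == 3L) dim(L)[2L] else ncol(L)
  if (nrow(voxel_coords) != nv || ncol(voxel_coords) != 3L)
    stop("voxel_coords must be voxels x 3", call. = FALSE)
  if (anyDuplicated(as.data.frame(voxel_coords)))
    stop("voxel coordinates must be unique", call. = FALSE)
  zero_col <- if (length(dim(L)) == 3L) {
    apply(L, 2L, function(m) all(m == 0))
  } else colSums(L^2) == 0
  if (any(zero_col)) stop("leadfield has all-zero voxel columns", call. = FALSE)
  structure(list(L = L, voxel_coords = voxel_coords,
                 grid_spacing = grid_spacing,
                 n_sensors = dim(L)[1L], n_voxels = nv),
            class = "leadfield_model")
}

#' @export
print.leadfield_model <- function(x, ...) {
  cat(sprintf("<leadfield_model> %d sensors x %d voxels, %g mm grid%s\n",
              x$n_sensors, x$n_voxels, x$grid_spacing,
              if (length(dim(x$L)) == 3L) " (free orientation)" else ""))
  invisible(x)
}

#' Sensor-level cross-spectral density matrix at one frequency
#'
#' CSD averaged over demeaned, tapered 1-s segments (FFT per segment,
#' outer products of the coefficients at the requested frequency bin).
#'
#' @param sensor_data numeric matrix, sensors x samples.
#' @param fs sampling rate in Hz.
#' @param freq frequency in Hz at which to evaluate the CSD.
#' @param spec a [segment_spec()].
#' @return a Hermitian positive semi-definite complex matrix
#'   (sensors x sensors) with attributes `freq` and `n_segments`. A
#'   warning is issued when there are fewer segments than sensors (rank
#'   deficiency; regularization required downstream).
#' @export
sensor_csd <- function(sensor_data, fs, freq, spec = segment_spec()) {
  stopifnot(is.matrix(sensor_data))
  coefs <- t(apply(sensor_data, 1L, .seg_coef_bin, fs = fs, freq = freq,
                   spec = spec))
  n_seg <- ncol(coefs)
  if (n_seg < nrow(sensor_data))
    warning("fewer segments than sensors: CSD is rank deficient; ",
            "use regularization in dics_filters()", call. = FALSE)
  csd <- coefs %*% Conj(t(coefs)) / n_seg
  csd <- (csd + Conj(t(csd))) / 2
  attr(csd, "freq") <- freq
  attr(csd, "n_segments") <- n_seg
  csd
}

#' DICS-style spatial filters from a CSD matrix and a leadfield
#'
#' Frequency-domain beamformer in the style of dynamic imaging of
#' coherent sources: with `C_r = Re(CSD) + reg_frac * mean(diag) * I`,
#' the filter for voxel `v` with leadfield column `l` is
#' `w = (l' C_r^-1 l)^-1 l' C_r^-1`, which satisfies the unit-gain
#' constraint `w l = 1` while minimizing output power. Free-orientation
#' leadfields are collapsed per voxel to the dominant singular direction
#' of the sensors x 3 gain block before filtering.
#'
#' @param csd Hermitian sensors x sensors CSD matrix (see [sensor_csd()]).
#' @param leadfield a [leadfield_model()].
#' @param reg_frac Tikhonov regularization as a fraction of the mean CSD
#'   diagonal (default 0.05).
#' @return an object of class `spatial_filters`: list with `W`
#'   (voxels x sensors), `frequency`, `regularization`.
#' @export
dics_filters <- function(csd, leadfield, reg_frac = 0.05) {
  stopifnot(inherits(leadfield, "leadfield_model"))
  if (reg_frac < 0) stop("reg_frac must be >= 0", call. = FALSE)
  if (max(Mod(csd - Conj(t(csd)))) > 1e-8 * max(Mod(csd)))
    stop("CSD matrix is not Hermitian", call. = FALSE)
  Cr <- Re(csd)
  n_sens <- nrow(Cr)
  Cr <- Cr + reg_frac * mean(diag(Cr)) * diag(n_sens)
  Ci <- tryCatch(solve(Cr), error = function(e)
    stop("CSD (real part) is singular; increase reg_frac", call. = FALSE))
  L <- leadfield$L
  nv <- leadfield$n_voxels
  Lfix <- if (length(dim(L)) == 3L) {
    vapply(seq_len(nv), function(v) {
      s <- svd(L[, v, ], nu = 1L, nv = 0L)
      s$u[, 1L] * s$d[1L]
    }, numeric(n_sens))
  } else L
  W <- matrix(0, nv, n_sens)
  CiL <- Ci %*% Lfix
  for (v in seq_len(nv)) {
    lv <- Lfix[, v]
    g <- sum(lv * CiL[, v])
    W[v, ] <- CiL[, v] / g
  }
  structure(list(W = W, frequency = attr(csd, "freq"),
                 regularization = reg_frac),
            class = "spatial_filters")
}

#' Reconstruct voxel time series from sensor data
#'
#' Applies beamformer coefficients to (typically band-pass filtered)
#' sensor data: voxel series = `W %*% sensor_data`. Purely linear.
#'
#' @param sensor_data numeric matrix, sensors x samples.
#' @param filters a [dics_filters()] result.
#' @return numeric matrix, voxels x samples.
#' @export
reconstruct_sources <- function(sensor_data, filters) {
  stopifnot(inherits(filters, "spatial_filters"), is.matrix(sensor_data))
  if (ncol(filters$W) != nrow(sensor_data))
    stop("sensor count mismatch between filters and data", call. = FALSE)
  filters$W %*% sensor_data
}

#' Write / read a leadfield model as portable files
#'
#' The gain matrix is stored as an RDS array next to a tab-separated
#' coordinate table (`x`, `y`, `z` in mm).
#'
#' @param lf a [leadfield_model()].
#' @param dir directory path.
#' @return `read_leadfield` returns a `leadfield_model`.
#' @export
write_leadfield <- function(lf, dir) {
  stopifnot(inherits(lf, "leadfield_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  saveRDS(lf$L, file.path(dir, "gain.rds"))
  coords <- as.data.frame(lf$voxel_coords)
  names(coords) <- c("x", "y", "z")
  write.table(coords, file.path(dir, "voxel_coords.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeLines(as.character(lf$grid_spacing),
             file.path(dir, "grid_spacing_mm.txt"))
  invisible(dir)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(dir) {
  L <- readRDS(file.path(dir, "gain.rds"))
  coords <- as.matrix(read.delim(file.path(dir, "voxel_coords.tsv")))
  spacing <- as.numeric(readLines(file.path(dir, "grid_spacing_mm.txt")))
  leadfield_model(L, coords, spacing)
}
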