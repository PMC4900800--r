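#' Extract lip-aperture geometry from binary mouth masks
#'
#' For each frame, the mouth-region mask is summarized by three series:
#' the aperture area (foreground pixel count), and the major and minor
#' axis lengths of the ellipse with the same normalized second central
#' moments as the region (the standard ellipse-equivalent definition).
#' The area series is the primary analysis signal; the minor (vertical)
#' axis carries nearly identical information for natural lip motion.
#'
#' @param masks a logical/0-1 numeric 3-D array (height x width x frames)
#'   or a list of equally sized binary matrices.
#' @param frame_rate video frame rate in Hz (typically 25).
#' @return an object of class `lip_geometry`: list with numeric vectors
#'   `area` (px^2), `major_axis`, `minor_axis` (px), and `frame_rate`.
#'   Empty frames yield zeros for all three values.
#' @export
extract_lip_geometry <- function(masks, frame_rate) {
  frames <- .as_frame_list(masks)
  if (length(frames) == 0L) stop("no frames supplied", call. = FALSE)
  dims <- dim(frames[[1L]])
  geom <- vapply(frames, function(fr) {
    if (!identical(dim(fr), dims))
      stop("frames differ in size", call. = FALSE)
    v <- as.vector(fr)
    if (!all(v %in% c(0, 1)))
      stop("frames must be binary (0/1 or logical)", call. = FALSE)
    idx <- which(fr != 0, arr.ind = TRUE)
    n <- nrow(idx)
    if (n == 0L) return(c(0, 0, 0))
    # central second moments of the pixel-coordinate cloud
    rc <- sweep(idx, 2L, colMeans(idx))
    mu <- crossprod(rc) / n
    ev <- eigen(mu, symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    # ellipse with matching moments: axis length = 4 sqrt(lambda)
    c(n, 4 * sqrt(ev[1L]), 4 * sqrt(ev[2L]))
  }, numeric(3L))
  structure(list(area = geom[1L, ], major_axis = geom[2L, ],
                 minor_axis = geom[3L, ], frame_rate = frame_rate),
            class = "lip_geometry")
}

.as_frame_list <- function(masks) {
  if (is.list(masks)) {
    lapply(masks, function(m) {
      if (is.logical(m)) storage.mode(m) <- "numeric"
      m
    })
  } else if (is.array(masks) && length(dim(masks)) == 3L) {
    m <- masks
    if (is.logical(m)) storage.mode(m) <- "numeric"
    lapply(seq_len(dim(m)[3L]), function(k) m[, , k])
  } else stop("masks must be a 3-D array or a list of matrices", call. = FALSE)
}

#' @export
print.lip_geometry <- function(x, ...) {
  cat(sprintf("<lip_geometry> %d frames @ %g fps; mean area %.0f px^2\n",
              length(x$area), x$frame_rate, mean(x$area)))
  invisible(x)
}

#' Coherence spectra among lip area and axis series
#'
#' Computes the Welch-segment coherence spectrum for the pairs
#' (area, minor), (area, major) and (minor, major). For natural lip
#' motion the area and the minor (vertical) axis are nearly perfectly
#' coherent across the speech-relevant 1-7 Hz range, which justifies
#' using the area series alone downstream.
#'
#' @param geom a [extract_lip_geometry()] result covering at least 60 s.
#' @param spec a [segment_spec()].
#' @return named list of three `coherence_spectrum` objects:
#'   `area_minor`, `area_major`, `minor_major`.
#' @export
axis_area_coherence <- function(geom, spec = segment_spec()) {
  stopifnot(inherits(geom, "lip_geometry"))
  fs <- geom$frame_rate
  n_seg <- tryCatch(length(.seg_starts(length(geom$area), fs, spec)),
                    error = function(e) 0L)
  if (n_seg < 30L)
    stop("geometry series too short: need at least 30 segments", call. = FALSE)
  pair <- function(a, b) coherence(cross_spectra(a, b, fs = fs, spec = spec))
  list(area_minor = pair(geom$area, geom$minor_axis),
       area_major = pair(geom$area, geom$major_axis),
       minor_major = pair(geom$minor_axis, geom$major_axis))
}

#' Write / read binary mask frames as PNG files
#'
#' Frames are written as `frame_000001.png` etc. (zero-padded indices)
#' into a directory, and read back in index order.
#'
#' @param masks 3-D array or list of binary matrices.
#' @param dir directory path (created if missing).
#' @return `write_lip_masks` returns the file paths invisibly;
#'   `read_lip_masks` returns a height x width x frames logical array.
#' @export
write_lip_masks <- function(masks, dir) {
  frames <- .as_frame_list(masks)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%06d.png", seq_along(frames)))
  for (i in seq_along(frames)) writePNG(frames[[i]], paths[i])
  invisible(paths)
}

#' @rdname write_lip_masks
#' @export
read_lip_masks <- function(dir) {
  paths <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (length(paths) == 0L) stop("no mask frames found in ", dir, call. = FALSE)
  frames <- lapply(paths, function(p) readPNG(p) > 0.5)
  array(unlist(frames), dim = c(dim(frames[[1L]]), length(frames)))
}

#' Write / read a lip geometry series as delimited text
#'
#' Tab-separated columns `frame`, `area`, `major`, `minor` with a header.
#'
#' @param geom a `lip_geometry` object.
#' @param path output file path.
#' @param frame_rate frame rate to attach on reading.
#' @return `read_lip_geometry` returns a `lip_geometry` object.
#' @export
write_lip_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "lip_geometry"))
  df <- data.frame(frame = seq_along(geom$area), area = geom$area,
                   major = geom$major_axis, minor = geom$minor_axis)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lip_geometry
#' @export
read_lip_geometry <- function(path, frame_rate) {
  df <- read.delim(path)
  structure(list(area = df$area, major_axis = df$major,
                 minor_axis = df$minor, frame_rate = frame_rate),
            class = "lip_geometry")
}
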