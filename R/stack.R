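#' Channel specification table
#'
#' Describes the detector channels of an ion-count stack. NanoSIMS detectors
#' are tuned to one secondary-ion species each; the conventional channel names
#' used throughout this package are `"13C12C"`, `"13C14N"`, `"32S"`, `"34S"`
#' and `"127I"`, but any unique labels are accepted.
#'
#' @param name character vector of channel labels (unique, non-empty).
#' @param detector_index integer vector of detector numbers (defaults to
#'   `seq_along(name)`).
#' @return a `data.frame` with columns `name` and `detector_index`.
#' @export
channel_spec <- function(name, detector_index = seq_along(name)) {
  name <- as.character(name)
  if (length(name) < 1L) stop("at least one channel must be present")
  if (anyDuplicated(name)) stop("channel names must be unique within a stack")
  if (length(detector_index) != length(name))
    stop("detector_index must match the number of channel names")
  data.frame(name = name, detector_index = as.integer(detector_index),
             stringsAsFactors = FALSE)
}

#' Multi-plane multi-channel ion-count stack
#'
#' Container for raw NanoSIMS acquisitions: one non-negative integer count
#' image per detector channel per sequential plane, plus acquisition metadata.
#' The physical pixel size is derived from the (square) field of view:
#' `pixel_size_nm = field_of_view_um * 1000 / width`.
#'
#' @param counts 4-dimensional array `[plane, channel, row, col]` of
#'   non-negative integer counts; images must be square.
#' @param channels a [channel_spec()] table (or character vector of names).
#' @param field_of_view_um positive edge length of the square field of view,
#'   in micrometres (typically 15--25).
#' @param dwell_time_ms positive per-pixel dwell time in milliseconds.
#' @param drift_offsets optional integer matrix of per-plane `(dy, dx)`
#'   shifts already applied (as recorded by [align_planes()]).
#' @return an object of class `ion_count_stack`.
#' @seealso [read_stack()], [write_stack()], [align_planes()], [accumulate()]
#' @export
ion_count_stack <- function(counts, channels, field_of_view_um, dwell_time_ms,
                            drift_offsets = NULL) {
  if (is.character(channels)) channels <- channel_spec(channels)
  if (!is.array(counts) || length(dim(counts)) != 4L)
    stop("counts must be a 4-axis array [plane, channel, row, col]")
  d <- dim(counts)
  if (d[1] < 1L) stop("plane count must be >= 1")
  if (d[2] != nrow(channels))
    stop("channel axis does not match the channel table")
  if (d[3] != d[4]) stop("images must be square (height == width)")
  if (!is_count_matrix(counts)) stop("invalid counts: must be non-negative integers")
  if (anyDuplicated(channels$name)) stop("channel names must be unique within a stack")
  if (!is.numeric(field_of_view_um) || field_of_view_um <= 0)
    stop("field_of_view_um must be positive")
  if (!is.numeric(dwell_time_ms) || dwell_time_ms <= 0)
    stop("dwell_time_ms must be positive")
  storage.mode(counts) <- "integer"
  if (is.null(drift_offsets))
    drift_offsets <- matrix(0L, nrow = d[1], ncol = 2L,
                            dimnames = list(NULL, c("dy", "dx")))
  structure(list(
    counts = counts,
    channels = channels,
    field_of_view_um = as.numeric(field_of_view_um),
    dwell_time_ms = as.numeric(dwell_time_ms),
    pixel_size_nm = field_of_view_um * 1000 / d[4],
    drift_offsets = drift_offsets
  ), class = "ion_count_stack")
}

#' @export
print.ion_count_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("ion_count_stack: %d plane(s), %d channel(s), %dx%d px\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  FOV %.3g um (%.5g nm/px), dwell %.3g ms\n",
              x$field_of_view_um, x$pixel_size_nm, x$dwell_time_ms))
  tot <- vapply(seq_len(d[2]), function(i) sum(x$counts[, i, , ]), numeric(1))
  cat("  total counts:",
      paste(sprintf("%s=%.4g", x$channels$name, tot), collapse = ", "), "\n")
  invisible(x)
}

channel_index <- function(x, name) {
  i <- match(name, x$channels$name)
  if (is.na(i)) stop(sprintf("missing channel: %s", name))
  i
}

plane_image <- function(stack, plane, channel) {
  i <- if (is.character(channel)) channel_index(stack, channel) else channel
  stack$counts[plane, i, , ]
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an ion-count stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are ordered plane-major then channel (page `(p-1)*n_channels + c`);
#' each page is a 16-bit unsigned-integer image. Acquisition metadata
#' (channel table, field of view, dwell time, plane count) goes to a JSON
#' sidecar with the same basename and extension `.json`.
#'
#' @param stack an [ion_count_stack()].
#' @param path output TIFF filename.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "ion_count_stack"))
  if (anyDuplicated(stack$channels$name))
    stop("channel names must be unique within a stack")
  d <- dim(stack$counts)
  if (max(stack$counts) > 65535L)
    stop("per-plane counts exceed the 16-bit page range")
  pages <- vector("list", d[1] * d[2])
  for (p in seq_len(d[1])) for (ch in seq_len(d[2]))
    pages[[(p - 1L) * d[2] + ch]] <- stack$counts[p, ch, , ] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(
    channels = stack$channels,
    field_of_view_um = stack$field_of_view_um,
    dwell_time_ms = stack$dwell_time_ms,
    n_planes = d[1]
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an ion-count stack written by [write_stack()]
#'
#' @param path TIFF filename; the JSON sidecar `<basename>.json` must exist.
#' @return an [ion_count_stack()]. Counts round-trip bit-identically.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("metadata missing: no JSON sidecar found")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  ch <- channel_spec(meta$channels$name, meta$channels$detector_index)
  n_planes <- as.integer(meta$n_planes)
  n_ch <- nrow(ch)
  if (length(pages) != n_planes * n_ch)
    stop(sprintf("layout error: %d pages but sidecar declares %d planes x %d channels",
                 length(pages), n_planes, n_ch))
  npx <- nrow(pages[[1]])
  counts <- array(0L, dim = c(n_planes, n_ch, npx, ncol(pages[[1]])))
  for (p in seq_len(n_planes)) for (cidx in seq_len(n_ch)) {
    pg <- pages[[(p - 1L) * n_ch + cidx]]
    if (!is_count_matrix(pg)) stop("invalid counts: negative or non-integer pixels")
    counts[p, cidx, , ] <- pg
  }
  ion_count_stack(counts, ch, meta$field_of_view_um, meta$dwell_time_ms)
}

## Circular cross-correlation peak between two equal-size images, returning the
## (dy, dx) shift to apply to img so it best matches ref.
xcorr_shift <- function(ref, img) {
  cc <- Re(stats::fft(stats::fft(ref) * Conj(stats::fft(img)), inverse = TRUE))
  idx <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
  d <- idx - 1L
  n <- c(nrow(ref), ncol(ref))
  ifelse(d > n / 2, d - n, d)
}

#' Rigid drift correction of sequential planes
#'
#' Sequential NanoSIMS planes drift by a few pixels as the stage and beam
#' wander; before accumulation each plane is realigned to the first plane by
#' the integer-pixel shift maximising the cross-correlation of one reference
#' channel (by default the structural CN image). The same shift is applied to
#' every channel of the plane; rows/columns shifted in are zero-filled.
#' Offsets larger than a quarter of the image width are treated as spurious
#' ("excessive drift" warning) and clamped.
#'
#' @param stack an [ion_count_stack()] with at least 2 planes.
#' @param reference_channel channel used to estimate the drift.
#' @return the realigned `ion_count_stack`; the per-plane `(dy, dx)` shifts
#'   applied are recorded in its `drift_offsets` field.
#' @export
align_planes <- function(stack, reference_channel = "13C14N") {
  stopifnot(inherits(stack, "ion_count_stack"))
  d <- dim(stack$counts)
  if (d[1] < 2L) stop("alignment needs at least 2 planes")
  ri <- channel_index(stack, reference_channel)
  ref <- stack$counts[1L, ri, , ]
  lim <- floor(0.25 * d[4])
  offsets <- matrix(0L, nrow = d[1], ncol = 2L,
                    dimnames = list(NULL, c("dy", "dx")))
  out <- stack$counts
  for (p in 2:d[1]) {
    off <- xcorr_shift(ref, stack$counts[p, ri, , ])
    if (any(abs(off) > lim)) {
      warning(sprintf("excessive drift in plane %d: offset (%d, %d) clamped",
                      p, off[1], off[2]))
      off <- pmin(pmax(off, -lim), lim)
    }
    offsets[p, ] <- as.integer(off)
    if (any(off != 0L))
      for (ch in seq_len(d[2]))
        out[p, ch, , ] <- shift_zero(stack$counts[p, ch, , ], off[1], off[2])
  }
  ion_count_stack(out, stack$channels, stack$field_of_view_um,
                  stack$dwell_time_ms, drift_offsets = offsets)
}

#' Accumulated (plane-summed) count image
#'
#' @param counts 3-axis integer array `[channel, row, col]`.
#' @param channels [channel_spec()] table.
#' @param pixel_size_nm physical pixel size.
#' @param n_planes_accumulated number of planes summed.
#' @param drift_offsets per-plane shifts that were applied before summation.
#' @return object of class `accumulated_image`.
#' @export
accumulated_image <- function(counts, channels, pixel_size_nm,
                              n_planes_accumulated = 1L, drift_offsets = NULL) {
  if (is.character(channels)) channels <- channel_spec(channels)
  stopifnot(length(dim(counts)) == 3L, dim(counts)[1] == nrow(channels))
  if (!is_count_matrix(counts)) stop("invalid counts: must be non-negative integers")
  storage.mode(counts) <- "integer"
  structure(list(
    counts = counts, channels = channels,
    pixel_size_nm = as.numeric(pixel_size_nm),
    n_planes_accumulated = as.integer(n_planes_accumulated),
    drift_offsets = drift_offsets
  ), class = "accumulated_image")
}

#' @export
print.accumulated_image <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("accumulated_image: %d channel(s), %dx%d px (%.5g nm/px), %d plane(s) summed\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$n_planes_accumulated))
  tot <- vapply(seq_len(d[1]), function(i) sum(x$counts[i, , ]), numeric(1))
  cat("  total counts:",
      paste(sprintf("%s=%.4g", x$channels$name, tot), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of an accumulated image
#' @param acc an [accumulated_image()].
#' @param name channel name.
#' @return count matrix.
#' @export
channel_image <- function(acc, name) {
  m <- acc$counts[channel_index(acc, name), , , drop = FALSE]
  dim(m) <- dim(acc$counts)[2:3]
  m
}

#' Accumulate planes of a stack into one count image per channel
#'
#' Pixel-wise sum over planes (typically after [align_planes()]); summing
#' raises the ion counts and thereby reduces the relative Poisson counting
#' error of every downstream ratio. With all-zero drift offsets the
#' per-channel total counts are conserved exactly.
#'
#' @param stack an [ion_count_stack()].
#' @return an [accumulated_image()].
#' @export
accumulate <- function(stack) {
  stopifnot(inherits(stack, "ion_count_stack"))
  d <- dim(stack$counts)
  out <- array(0L, dim = d[2:4])
  for (ch in seq_len(d[2]))
    out[ch, , ] <- colSums(array(stack$counts[, ch, , , drop = FALSE],
                                 c(d[1], d[3], d[4])))
  accumulated_image(out, stack$channels, stack$pixel_size_nm,
                    n_planes_accumulated = d[1],
                    drift_offsets = stack$drift_offsets)
}
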