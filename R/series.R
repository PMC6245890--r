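#' Dynamic perfusion image series
#'
#' Container for a dynamic short-axis perfusion acquisition: a 4-D array
#' indexed `[row, col, slice, frame]`, the frame times in seconds from the
#' start of the series, and the in-plane pixel size in mm. All pixel indices
#' in this package are 1-based and inclusive, following R convention.
#'
#' @param data numeric 4-D array `[row, col, slice, frame]` (a 3-D array is
#'   promoted to a single slice).
#' @param times frame times (s), strictly increasing, one per frame.
#' @param pixel_size in-plane pixel edge length (mm).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(data, times, pixel_size = 1.9) {
  if (length(dim(data)) == 3)
    dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3])
  if (length(dim(data)) != 4)
    stop("'data' must be a 4-D [row, col, slice, frame] array")
  if (length(times) != dim(data)[4])
    stop("length(times) must equal the number of frames")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  structure(list(data = data, times = as.numeric(times),
                 pixel_size = pixel_size),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_series> %d x %d px, %d slice(s), %d frames, dt = %.3g s, pixel %.3g mm\n",
    d[1], d[2], d[3], d[4], if (d[4] > 1) x$times[2] - x$times[1] else NA,
    x$pixel_size))
  invisible(x)
}

#' @export
dim.dynamic_series <- function(x) dim(x$data)

n_frames <- function(series) dim(series$data)[4]
n_slices <- function(series) dim(series$data)[3]

frame_image <- function(series, slice, frame) series$data[, , slice, frame]

#' Write a dynamic series as NIfTI plus a JSON sidecar
#'
#' The image goes to `<path>` as a 4-D NIfTI volume (double precision, so
#' round trips are lossless); frame times and pixel size go to a JSON
#' sidecar at `<path without .nii/.nii.gz>.json`.
#'
#' @param series a [dynamic_series()].
#' @param path output NIfTI path (`.nii` or `.nii.gz`).
#' @return Invisibly, the sidecar path.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "dynamic_series"))
  RNifti::writeNifti(series$data, path, datatype = "double")
  side <- sidecar_path(path)
  jsonlite::write_json(
    list(frame_times = series$times, pixel_size = series$pixel_size),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read a dynamic series written by [write_series()]
#'
#' @param path NIfTI path; the JSON sidecar with frame times must exist
#'   alongside it (its absence is an error, never a silent default).
#' @return A [dynamic_series()].
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("frame-time sidecar not found: ", side,
         " (required field 'frame_times')")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$frame_times))
    stop("sidecar ", side, " is missing required field 'frame_times'")
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  dynamic_series(arr, times = as.numeric(meta$frame_times),
                 pixel_size = if (!is.null(meta$pixel_size))
                   meta$pixel_size else 1.9)
}
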