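#' Multi-channel time-lapse movie
#'
#' @param channels Named list of 3-D numeric arrays (`height x width x
#'   frames`) of nonnegative intensities; all channels must share dimensions.
#' @param pixel_size_um,frame_interval_min Physical calibration (> 0).
#' @param time_origin_min Time of the first frame (default 0).
#' @return A `movie` object.
#' @export
movie <- function(channels, pixel_size_um, frame_interval_min,
                  time_origin_min = 0) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))),
            pixel_size_um > 0, frame_interval_min > 0)
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a height x width x frames array")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("channels differ in dimensions")
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min,
                 time_origin_min = time_origin_min),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<movie> %s | %d x %d px, %d frames @ %.3g min, %.3g um/px\n",
              paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$frame_interval_min, x$pixel_size_um))
  invisible(x)
}

#' Frame times of a movie
#' @param x A [movie()].
#' @return Numeric vector of frame times (min).
#' @export
frame_times <- function(x) {
  nt <- dim(x$channels[[1]])[3]
  x$time_origin_min + (seq_len(nt) - 1) * x$frame_interval_min
}
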