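#' Write a movie as multi-page TIFF stacks
#'
#' One TIFF per channel plus a YAML sidecar with the calibration, channel
#' file names, and the intensity scale used to map intensities into the
#' TIFF range (intensities are divided by `intensity_scale` on write and
#' multiplied back on read).
#'
#' @param movie A [movie()].
#' @param dir Output directory (created if needed).
#' @param basename File name stem.
#' @param bits 16 (integer) or 32 (float) samples per pixel.
#' @return Invisibly, the sidecar path.
#' @export
write_movie <- function(movie, dir, basename = "movie", bits = 16) {
  stopifnot(inherits(movie, "movie"), bits %in% c(16, 32))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mx <- max(1, vapply(movie$channels, max, 1))
  # when intensities fit the integer range, scaling by 2^bits - 1 makes the
  # round trip exact for integer-valued data
  scale <- if (bits == 16 && mx <= 65535) 65535 else mx
  files <- list()
  for (ch in names(movie$channels)) {
    arr <- movie$channels[[ch]]
    fn <- sprintf("%s_%s.tif", basename, ch)
    # noise can dip below zero; stored intensities are clamped at zero
    pages <- lapply(seq_len(dim(arr)[3]), function(f) pmax(arr[, , f], 0) / scale)
    tiff::writeTIFF(pages, file.path(dir, fn), bits.per.sample = bits)
    files[[ch]] <- fn
  }
  sidecar <- file.path(dir, sprintf("%s.yaml", basename))
  yaml::write_yaml(list(channels = files,
                        pixel_size_um = movie$pixel_size_um,
                        frame_interval_min = movie$frame_interval_min,
                        time_origin_min = movie$time_origin_min,
                        intensity_scale = scale,
                        bits = bits), sidecar)
  invisible(sidecar)
}

#' Read a movie from multi-page TIFF stacks
#'
#' Calibration must be supplied either through the YAML sidecar written by
#' [write_movie()] or explicitly; it is never guessed.
#'
#' @param paths Named character vector/list of per-channel TIFF paths, or a
#'   single sidecar YAML path.
#' @param pixel_size_um,frame_interval_min Calibration (required when
#'   `paths` are raw TIFFs).
#' @param time_origin_min Time of the first frame.
#' @param intensity_scale Factor multiplied into the stored values.
#' @param bits Bit depth of integer TIFFs (8 or 16); inferred from the data
#'   range when `NULL`.
#' @return A [movie()].
#' @export
read_movie <- function(paths, pixel_size_um = NULL, frame_interval_min = NULL,
                       time_origin_min = 0, intensity_scale = 1, bits = NULL) {
  if (length(paths) == 1 && grepl("\\.ya?ml$", paths[[1]])) {
    sc <- yaml::read_yaml(paths[[1]])
    base <- dirname(paths[[1]])
    paths <- lapply(sc$channels, function(f) file.path(base, f))
    pixel_size_um <- sc$pixel_size_um
    frame_interval_min <- sc$frame_interval_min
    time_origin_min <- sc$time_origin_min
    intensity_scale <- sc$intensity_scale
    bits <- sc$bits
  }
  if (is.null(pixel_size_um) || is.null(frame_interval_min))
    stop("calibration (pixel_size_um, frame_interval_min) is required")
  channels <- lapply(paths, function(p) {
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(pg) {
      if (length(dim(pg)) == 3) pg <- pg[, , 1]  # collapse grayscale-written-as-RGB
      pg
    })
    is_int <- is.integer(pages[[1]])
    arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
    for (f in seq_along(pages)) arr[, , f] <- pages[[f]]
    # integer TIFFs arrive as raw counts; floats as stored fractions
    if (is_int) {
      b <- if (!is.null(bits)) bits else if (max(arr) > 255) 16 else 8
      arr <- arr / (2^b - 1)
    }
    arr * intensity_scale
  })
  dims <- vapply(channels, function(a) paste(dim(a), collapse = "x"), "")
  if (length(unique(dims)) != 1)
    stop("channels differ in dimensions: ", paste(dims, collapse = " vs "))
  movie(channels, pixel_size_um, frame_interval_min, time_origin_min)
}

#' Write ground truth as per-cycle TIFF maps plus a JSON table
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory.
#' @param basename File name stem.
#' @return Invisibly, the JSON path.
#' @export
write_ground_truth <- function(truth, dir, basename = "truth") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(truth$exit_maps, na.rm = TRUE)
  for (c_i in seq_len(truth$n_cycles)) {
    em <- truth$entry_maps[, , c_i]; xm <- truth$exit_maps[, , c_i]
    em[is.na(em)] <- 0; xm[is.na(xm)] <- 0
    tiff::writeTIFF(em / scale, file.path(dir, sprintf("%s_entry_c%02d.tif", basename, c_i)),
                    bits.per.sample = 32L)
    tiff::writeTIFF(xm / scale, file.path(dir, sprintf("%s_exit_c%02d.tif", basename, c_i)),
                    bits.per.sample = 32L)
  }
  pm <- truth$pacemaker_table
  pm$firing_times_min <- NULL
  path <- file.path(dir, sprintf("%s.json", basename))
  jsonlite::write_json(list(n_cycles = truth$n_cycles, time_scale_min = scale,
                            pacemakers = pm, nuclei = truth$nucleus_truth),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a sources table as CSV
#'
#' Columns follow the standard source schema (experiment, cycle, position,
#' onset, class, structure distances, delta-cycle time).
#'
#' @param sources Tibble of (classified) sources.
#' @param path Output CSV path.
#' @export
write_sources_csv <- function(sources, path) {
  utils::write.csv(as.data.frame(sources), path, row.names = FALSE)
  invisible(path)
}
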