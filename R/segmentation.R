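#' Segmentation parameters
#'
#' @param theta_entry Normalised level whose first downward crossing defines
#'   mitotic entry (and whose first upward crossing after entry defines
#'   exit). A fixed normalised level makes front timing independent of local
#'   amplitude, so kymograph slopes are unbiased.
#' @param smooth_window Centred moving-average window (frames) applied to
#'   each pixel trace before cycle decomposition.
#' @param spatial_sigma_px Gaussian pre-smoothing of each frame (px; 0
#'   disables). Suppresses the early bias that per-pixel noise would induce
#'   in region onset times (which are minima over many pixels).
#' @param min_range_frac A pixel is invalid when its smoothed dynamic range
#'   is below this fraction of the well-wide 95th-percentile range.
#' @param min_mitotic_frames Minimum length (frames) of a sub-midline run
#'   accepted as a mitotic episode.
#' @param max_cycles Upper bound on cycles extracted per pixel.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(theta_entry = 0.75, smooth_window = 3,
                                spatial_sigma_px = 1, min_range_frac = 0.25,
                                min_mitotic_frames = 2, max_cycles = 30) {
  stopifnot(theta_entry > 0.5, theta_entry < 1, smooth_window >= 1)
  structure(list(theta_entry = theta_entry, smooth_window = as.integer(smooth_window),
                 spatial_sigma_px = spatial_sigma_px,
                 min_range_frac = min_range_frac,
                 min_mitotic_frames = as.integer(min_mitotic_frames),
                 max_cycles = as.integer(max_cycles)),
            class = "segmentation_params")
}

#' Well mask from a movie
#'
#' Thresholds the temporal median of the tubulin channel (Otsu, hence
#' invariant to global intensity scaling), keeps the largest connected
#' bright region, and fills holes.
#'
#' @param movie A [movie()].
#' @param channel Channel name (default `"tubulin"`).
#' @param n_sample_frames Number of evenly spaced frames used for the
#'   temporal median.
#' @return A [well_geometry()].
#' @export
make_well_mask <- function(movie, channel = "tubulin", n_sample_frames = 7) {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("channel not found: ", channel)
  nt <- dim(arr)[3]
  idx <- unique(round(seq(1, nt, length.out = min(n_sample_frames, nt))))
  med <- apply(arr[, , idx, drop = FALSE], c(1, 2), median)
  mx <- max(med)
  if (mx <= 0) stop("empty mask: movie has no signal")
  thr <- EBImage::otsu(med / mx, range = c(0, 1))
  bin <- med / mx > thr
  if (!any(bin)) stop("empty mask: no pixels above threshold")
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- EBImage::fillHull(lab == keep) > 0
  well_geometry(nrow(mask), ncol(mask), movie$pixel_size_um, mask = mask)
}

#' Decompose a single intensity trace into cycles
#'
#' Cycles are delimited by mitotic episodes of the smoothed, min-max
#' normalised trace; within each cycle window the trace is re-normalised and
#' entry/exit times are read off as threshold crossings with sub-frame
#' linear interpolation. See [segmentation_params()].
#'
#' @param trace Numeric vector of intensities (one per frame).
#' @param frame_interval Minutes per frame.
#' @param params A [segmentation_params()].
#' @param time_origin_min Time of the first sample.
#' @return Tibble with one row per detected cycle: `cycle`, `entry_min`,
#'   `exit_min`, `complete`.
#' @export
decompose_cycles <- function(trace, frame_interval, params = segmentation_params(),
                             time_origin_min = 0) {
  stopifnot(length(trace) >= 2)
  rng <- diff(range(trace))
  res <- decompose_cycles_cpp(matrix(trace, nrow = 1), frame_interval,
                              time_origin_min, params$theta_entry,
                              params$smooth_window,
                              params$min_range_frac * rng,
                              params$min_mitotic_frames, params$max_cycles)
  n <- res$n_cycles[1]
  if (!res$valid[1] || n == 0)
    return(tibble::tibble(cycle = integer(), entry_min = numeric(),
                          exit_min = numeric(), complete = logical()))
  tibble::tibble(cycle = seq_len(n),
                 entry_min = res$entry[1, seq_len(n)],
                 exit_min = res$exit[1, seq_len(n)],
                 complete = !is.na(res$exit[1, seq_len(n)]))
}

#' Per-pixel cycle decomposition of a movie
#'
#' Runs [decompose_cycles()] at every valid pixel of the (optionally
#' pre-smoothed) tubulin channel and aligns cycles across pixels by index.
#' Pixels whose number of detected cycles deviates from the well-wide mode
#' are marked invalid, which keeps per-cycle maps consistently indexed.
#'
#' @param movie A [movie()].
#' @param geometry Optional [well_geometry()]; computed with
#'   [make_well_mask()] when absent.
#' @param channel Channel name.
#' @param params A [segmentation_params()].
#' @return A `cycle_series` object with `entry`/`exit` arrays
#'   (`height x width x n_cycles`), a `valid` matrix, per-pixel cycle counts
#'   and the movie calibration.
#' @export
segment_movie <- function(movie, geometry = NULL, channel = "tubulin",
                          params = segmentation_params()) {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("channel not found: ", channel)
  if (is.null(geometry)) geometry <- make_well_mask(movie, channel)
  h <- dim(arr)[1]; w <- dim(arr)[2]; nt <- dim(arr)[3]
  stopifnot(geometry$height_px == h, geometry$width_px == w)

  if (params$spatial_sigma_px > 0) {
    sm <- array(0, dim(arr))
    for (f in seq_len(nt))
      sm[, , f] <- EBImage::gblur(arr[, , f], sigma = params$spatial_sigma_px,
                                  boundary = "replicate")
    arr <- sm
  }

  mask_idx <- which(geometry$mask)
  traces <- matrix(aperm(arr, c(3, 1, 2)), nrow = nt)  # nt x (h*w)
  traces <- t(traces[, mask_idx, drop = FALSE])        # npx x nt
  ranges <- apply(traces, 1, function(v) diff(range(v)))
  min_range <- params$min_range_frac * quantile(ranges, 0.95, names = FALSE)

  res <- decompose_cycles_cpp(traces, movie$frame_interval_min,
                              movie$time_origin_min, params$theta_entry,
                              params$smooth_window, min_range,
                              params$min_mitotic_frames, params$max_cycles)

  counts <- res$n_cycles
  valid_px <- res$valid & counts > 0
  modal <- if (any(valid_px)) {
    tab <- table(counts[valid_px])
    as.integer(names(tab)[which.max(tab)])
  } else 0L
  valid_px <- valid_px & counts == modal
  n_cycles <- modal

  entry <- array(NA_real_, c(h, w, max(n_cycles, 1L)))
  exitm <- array(NA_real_, c(h, w, max(n_cycles, 1L)))
  if (n_cycles > 0) {
    for (c_i in seq_len(n_cycles)) {
      e <- rep(NA_real_, h * w); x <- rep(NA_real_, h * w)
      e[mask_idx[valid_px]] <- res$entry[valid_px, c_i]
      x[mask_idx[valid_px]] <- res$exit[valid_px, c_i]
      entry[, , c_i] <- e
      exitm[, , c_i] <- x
    }
  }
  valid <- matrix(FALSE, h, w)
  valid[mask_idx[valid_px]] <- TRUE

  structure(list(entry = entry, exit = exitm, valid = valid,
                 n_cycles = n_cycles, counts_px = counts,
                 geometry = geometry,
                 pixel_size_um = movie$pixel_size_um,
                 frame_interval_min = movie$frame_interval_min),
            class = "cycle_series")
}

#' @export
print.cycle_series <- function(x, ...) {
  cat(sprintf("<cycle_series> %d cycle(s), %d valid px\n", x$n_cycles, sum(x$valid)))
  invisible(x)
}

#' Mitotic-entry-time map for one cycle
#'
#' @param series A `cycle_series` from [segment_movie()].
#' @param cycle Cycle index.
#' @return An `entry_time_map`: per-pixel entry times (min, `NA` where
#'   undefined) plus calibration.
#' @export
entry_time_map <- function(series, cycle) {
  stopifnot(inherits(series, "cycle_series"),
            cycle >= 1, cycle <= series$n_cycles)
  structure(list(times = series$entry[, , cycle], cycle = as.integer(cycle),
                 pixel_size_um = series$pixel_size_um,
                 frame_interval_min = series$frame_interval_min),
            class = "entry_time_map")
}

#' Nucleus detection parameters
#' @param sigma_small_px,sigma_large_px Band-pass (difference-of-Gaussians)
#'   scales.
#' @param threshold_mads Detection threshold in MADs of the band-passed
#'   in-mask intensities per frame.
#' @param link_radius_px Maximum frame-to-frame displacement when linking.
#' @param min_persist_frames Minimum track length (frames); replaces the
#'   manual curation of nuclei with a temporal persistence filter.
#' @return A `nucleus_params` object.
#' @export
nucleus_params <- function(sigma_small_px = 1.5, sigma_large_px = 6,
                           threshold_mads = 8, link_radius_px = 4,
                           min_persist_frames = 3) {
  structure(list(sigma_small_px = sigma_small_px, sigma_large_px = sigma_large_px,
                 threshold_mads = threshold_mads, link_radius_px = link_radius_px,
                 min_persist_frames = as.integer(min_persist_frames)),
            class = "nucleus_params")
}

#' Detect nuclei in the NLS-reporter channel
#'
#' Nuclei are bright blobs of the nuclear reporter that accumulate during
#' interphase and disperse at nuclear envelope breakdown. Each frame is
#' band-pass filtered, thresholded, and blob centroids are linked across
#' frames; tracks shorter than the persistence filter are discarded. Tracks
#' are assigned to the cycle whose interphase contains their midpoint, using
#' the entry/exit maps of `series`.
#'
#' @param movie A [movie()] with an `nls` channel.
#' @param series A `cycle_series` from [segment_movie()].
#' @param params A [nucleus_params()].
#' @param channel NLS channel name.
#' @return Tibble (cycle, x_um, y_um, t_first_min, t_last_min, intensity).
#' @export
detect_nuclei <- function(movie, series, params = nucleus_params(),
                          channel = "nls") {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("channel not found: ", channel)
  h <- dim(arr)[1]; w <- dim(arr)[2]; nt <- dim(arr)[3]
  mask <- series$geometry$mask
  s <- movie$pixel_size_um
  times <- frame_times(movie)

  detections <- vector("list", nt)
  for (f in seq_len(nt)) {
    fr <- arr[, , f]
    bp <- EBImage::gblur(fr, params$sigma_small_px, boundary = "replicate") -
      EBImage::gblur(fr, params$sigma_large_px, boundary = "replicate")
    vals <- bp[mask]
    thr <- median(vals) + params$threshold_mads * mad(vals)
    bin <- bp > thr & mask
    if (!any(bin)) next
    lab <- EBImage::bwlabel(bin)
    idx <- which(lab > 0)
    if (!length(idx)) next
    li <- lab[idx]
    wi <- fr[idx]
    rr <- ((idx - 1) %% h) + 1
    cc <- ((idx - 1) %/% h) + 1
    sw <- tapply(wi, li, sum)
    xs <- tapply(wi * (cc - 0.5) * s, li, sum) / sw
    ys <- tapply(wi * (rr - 0.5) * s, li, sum) / sw
    pk <- tapply(wi, li, max)
    detections[[f]] <- data.frame(frame = f, x_um = as.numeric(xs),
                                  y_um = as.numeric(ys), peak = as.numeric(pk))
  }

  # greedy frame-to-frame linking
  tracks <- list()   # each: list(x, y, frames, peaks, active)
  link_um <- params$link_radius_px * s
  for (f in seq_len(nt)) {
    det <- detections[[f]]
    active <- which(vapply(tracks, function(tr) tr$active &&
                             f - tr$frames[length(tr$frames)] <= 1L, TRUE))
    used <- logical(if (is.null(det)) 0 else nrow(det))
    for (ti in active) {
      tr <- tracks[[ti]]
      if (is.null(det) || !nrow(det)) { tracks[[ti]]$active <- FALSE; next }
      lx <- tr$x[length(tr$x)]; ly <- tr$y[length(tr$y)]
      d <- sqrt((det$x_um - lx)^2 + (det$y_um - ly)^2)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= link_um) {
        used[j] <- TRUE
        tracks[[ti]]$x <- c(tr$x, det$x_um[j])
        tracks[[ti]]$y <- c(tr$y, det$y_um[j])
        tracks[[ti]]$frames <- c(tr$frames, f)
        tracks[[ti]]$peaks <- c(tr$peaks, det$peak[j])
      } else {
        tracks[[ti]]$active <- FALSE
      }
    }
    if (!is.null(det) && nrow(det)) {
      for (j in which(!used)) {
        tracks[[length(tracks) + 1L]] <- list(x = det$x_um[j], y = det$y_um[j],
                                              frames = f, peaks = det$peak[j],
                                              active = TRUE)
      }
    }
  }

  keep <- Filter(function(tr) length(tr$frames) >= params$min_persist_frames, tracks)
  if (!length(keep))
    return(tibble::tibble(cycle = integer(), x_um = numeric(), y_um = numeric(),
                          t_first_min = numeric(), t_last_min = numeric(),
                          intensity = numeric()))

  out <- lapply(keep, function(tr) {
    wgt <- tr$peaks / sum(tr$peaks)
    x <- sum(tr$x * wgt); y <- sum(tr$y * wgt)
    t_first <- times[tr$frames[1]]; t_last <- times[tr$frames[length(tr$frames)]]
    geom <- series$geometry
    px <- um_to_pixel(geom, x, y)
    t_mid <- (t_first + t_last) / 2
    cyc <- NA_integer_
    for (c_i in seq_len(series$n_cycles)) {
      t_entry <- series$entry[px[1, "row"], px[1, "col"], c_i]
      t_prev_exit <- if (c_i == 1) -Inf else series$exit[px[1, "row"], px[1, "col"], c_i - 1]
      if (is.na(t_entry)) next
      if (!is.na(t_prev_exit) && t_mid > t_prev_exit && t_mid <= t_entry + 1e-9) {
        cyc <- c_i; break
      }
      if (c_i == 1 && t_mid <= t_entry) { cyc <- 1L; break }
    }
    data.frame(cycle = cyc, x_um = x, y_um = y, t_first_min = t_first,
               t_last_min = t_last, intensity = max(tr$peaks))
  })
  tibble::as_tibble(do.call(rbind, out))
}

#' Geometric-mean per-cycle fold change of nucleus counts
#'
#' @param counts Nucleus counts per cycle (length >= 2).
#' @return `(last/first)^(1/(n-1))`.
#' @export
nucleus_fold_change <- function(counts) {
  stopifnot(length(counts) >= 2, counts[1] > 0)
  (counts[length(counts)] / counts[1])^(1 / (length(counts) - 1))
}
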