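new_kymograph <- function(mat, r_um, t_min, origin, kind, flagged_bins = logical(nrow(mat))) {
  stopifnot(nrow(mat) == length(r_um), ncol(mat) == length(t_min))
  structure(list(mat = mat, r_um = r_um, t_min = t_min, origin = origin,
                 kind = kind, flagged_bins = flagged_bins),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph:%s> %d bins x %d frames, r [%.0f, %.0f] um, t [%.1f, %.1f] min\n",
              x$kind, nrow(x$mat), ncol(x$mat), min(x$r_um), max(x$r_um),
              min(x$t_min), max(x$t_min)))
  invisible(x)
}

#' Linear kymograph along a slice
#'
#' Mean intensity across the slice width, per position bin per frame, as in
#' cross-section kymographs of a well.
#'
#' @param movie A [movie()].
#' @param p0_um,p1_um Slice endpoints, `c(x, y)` in micrometres.
#' @param channel Channel name.
#' @param width_px Number of parallel sample lines averaged across the slice
#'   (odd; default 3).
#' @param bin_width_um Position bin width (defaults to the pixel size).
#' @param geometry Optional [well_geometry()]; when supplied the slice must
#'   lie inside the mask.
#' @param t0_min Time origin subtracted from the frame times (e.g. a source
#'   onset).
#' @return A `kymograph`; `r_um` is distance along the slice from `p0_um`.
#' @export
linear_kymograph <- function(movie, p0_um, p1_um, channel = "tubulin",
                             width_px = 3, bin_width_um = NULL,
                             geometry = NULL, t0_min = 0) {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("channel not found: ", channel)
  s <- movie$pixel_size_um
  if (is.null(bin_width_um)) bin_width_um <- s
  h <- dim(arr)[1]; w <- dim(arr)[2]; nt <- dim(arr)[3]
  d <- sqrt(sum((p1_um - p0_um)^2))
  stopifnot(d > 0, bin_width_um > 0)
  u <- (p1_um - p0_um) / d
  perp <- c(-u[2], u[1])
  nbins <- ceiling(d / bin_width_um)
  r <- (seq_len(nbins) - 0.5) * bin_width_um
  offs <- (seq_len(width_px) - (width_px + 1) / 2) * s

  mat <- matrix(NA_real_, nbins, nt)
  rows <- matrix(NA_integer_, nbins, width_px)
  cols <- matrix(NA_integer_, nbins, width_px)
  for (i in seq_len(nbins)) {
    for (k in seq_len(width_px)) {
      p <- p0_um + u * r[i] + perp * offs[k]
      cc <- ceiling(p[1] / s); rr <- ceiling(p[2] / s)
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w) {
        rows[i, k] <- rr; cols[i, k] <- cc
      }
    }
  }
  if (!is.null(geometry)) {
    centre_ok <- vapply(seq_len(nbins), function(i) {
      k <- (width_px + 1) %/% 2
      !is.na(rows[i, k]) && geometry$mask[rows[i, k], cols[i, k]]
    }, TRUE)
    if (!all(centre_ok)) stop("slice extends outside the well mask")
  }
  for (f in seq_len(nt)) {
    fr <- arr[, , f]
    for (i in seq_len(nbins)) {
      ok <- !is.na(rows[i, ])
      if (any(ok)) mat[i, f] <- mean(fr[cbind(rows[i, ok], cols[i, ok])])
    }
  }
  new_kymograph(mat, r, frame_times(movie) - t0_min,
                origin = list(p0_um = p0_um, p1_um = p1_um, t0_min = t0_min),
                kind = "linear")
}

#' Radial kymograph around a source
#'
#' Mean intensity over each annulus `[r, r + bin)` centred on a source, per
#' frame, with the time axis re-origined at the source onset. Annuli are
#' clipped to the well mask; bins whose full annulus is not entirely inside
#' the mask are flagged (partially sampled).
#'
#' @param movie A [movie()].
#' @param center_um Source position `c(x, y)` (um).
#' @param r_max_um Outer radius (um).
#' @param channel Channel name.
#' @param bin_width_um Annulus width (default 13 um, two pixels at the 5x
#'   objective scale).
#' @param geometry Optional [well_geometry()] for mask clipping.
#' @param t0_min Source onset (min), subtracted from the frame times.
#' @return A `kymograph`; `r_um` holds annulus mid-radii.
#' @export
radial_kymograph <- function(movie, center_um, r_max_um, channel = "tubulin",
                             bin_width_um = 13, geometry = NULL, t0_min = 0) {
  arr <- movie$channels[[channel]]
  if (is.null(arr)) stop("channel not found: ", channel)
  s <- movie$pixel_size_um
  h <- dim(arr)[1]; w <- dim(arr)[2]; nt <- dim(arr)[3]
  mask <- if (is.null(geometry)) matrix(TRUE, h, w) else geometry$mask
  if (!is.null(geometry)) {
    px <- um_to_pixel(geometry, center_um[1], center_um[2])
    if (!mask[px[1, "row"], px[1, "col"]]) stop("source outside the well mask")
  }
  co_x <- matrix(rep((seq_len(w) - 0.5) * s, each = h), h, w)
  co_y <- matrix(rep((seq_len(h) - 0.5) * s, w), h, w)
  dd <- sqrt((co_x - center_um[1])^2 + (co_y - center_um[2])^2)
  nbins <- ceiling(r_max_um / bin_width_um)
  bin <- floor(dd / bin_width_um) + 1L
  sel <- which(mask & bin <= nbins)
  bin_sel <- bin[sel]
  counts <- tabulate(bin_sel, nbins)
  # a bin is partial when part of its annulus lies outside mask or grid
  full_counts <- tabulate(bin[bin <= nbins], nbins)
  edge_clip <- any(dd[!mask] < r_max_um) ||
    center_um[1] - r_max_um < 0 || center_um[2] - r_max_um < 0 ||
    center_um[1] + r_max_um > w * s || center_um[2] + r_max_um > h * s
  flagged <- counts < full_counts | counts == 0
  if (edge_clip) flagged <- flagged | (seq_len(nbins) * bin_width_um >
                                         min(center_um[1], center_um[2],
                                             w * s - center_um[1], h * s - center_um[2]))
  mat <- matrix(NA_real_, nbins, nt)
  for (f in seq_len(nt)) {
    v <- arr[, , f][sel]
    sums <- rep(0, nbins)
    tb <- tapply(v, bin_sel, sum)
    sums[as.integer(names(tb))] <- tb
    mat[, f] <- ifelse(counts > 0, sums / counts, NA_real_)
  }
  new_kymograph(mat, (seq_len(nbins) - 0.5) * bin_width_um,
                frame_times(movie) - t0_min,
                origin = list(center_um = center_um, t0_min = t0_min),
                kind = "radial", flagged_bins = flagged)
}

# first threshold crossing of a normalised trace; dir = "down" or "up";
# for "up", search starts after the first down crossing (mitotic entry)
crossing_time <- function(z, t, theta, dir, t_search_min) {
  n <- length(z)
  start <- which(t >= t_search_min)[1]
  if (is.na(start)) return(NA_real_)
  k_down <- NA_integer_
  for (k in start:max(start, n - 1)) {
    if (k >= n) break
    if (z[k] >= theta && z[k + 1] < theta) { k_down <- k; break }
  }
  if (dir == "down") {
    if (is.na(k_down)) return(NA_real_)
    return(t[k_down] + (t[k_down + 1] - t[k_down]) *
             (z[k_down] - theta) / (z[k_down] - z[k_down + 1]))
  }
  if (is.na(k_down)) return(NA_real_)
  for (k in (k_down + 1):max(k_down + 1, n - 1)) {
    if (k >= n) break
    if (z[k] < theta && z[k + 1] >= theta)
      return(t[k] + (t[k + 1] - t[k]) * (theta - z[k]) / (z[k + 1] - z[k]))
  }
  NA_real_
}

#' Fit a front speed to a kymograph
#'
#' Per position bin, the front time is the crossing of the normalised
#' intensity trace through `theta` (downward for the mitotic-entry front,
#' upward -- after entry -- for the mitotic-exit front), with sub-frame
#' linear interpolation. The fit window runs from the first bin beyond the
#' source footprint to the bin where the front stops advancing (wave
#' collision or concerted bulk entry, detected as a stalled front time), and
#' the speed is the least-squares slope of distance on time.
#'
#' @param kym A `kymograph`.
#' @param phase `"entry"` or `"exit"`.
#' @param theta Normalised crossing level (same convention as segmentation).
#' @param r_min_um Bins at or below this distance are excluded (source
#'   footprint).
#' @param t_search_min Crossings are searched from this time on the
#'   kymograph's time axis (default: its start). With the axis re-origined
#'   at the source onset, a small negative value selects the focal mitosis.
#' @param fold_at_um For linear slices through a source: fold the position
#'   axis at this offset and average the two arms.
#' @param invert Set `TRUE` when the wave raises rather than lowers the
#'   signal (e.g. an activator field): swaps the crossing directions.
#' @param stall_eps_min Minimum front-time increment per bin; the fit stops
#'   at the first smaller increment.
#' @param r2_flag Fits with R-squared below this are flagged.
#' @return A `kymograph_fit`: `speed_um_per_min`, `intercept_min`,
#'   `r_squared`, `n_points`, `front` (tibble of r, t), `flagged`.
#' @export
fit_front_speed <- function(kym, phase = c("entry", "exit"), theta = 0.75,
                            r_min_um = 0, t_search_min = NULL,
                            fold_at_um = NULL, invert = FALSE,
                            stall_eps_min = 0.04, r2_flag = 0.9) {
  phase <- match.arg(phase)
  stopifnot(inherits(kym, "kymograph"))
  if (is.null(t_search_min)) t_search_min <- min(kym$t_min)
  dir <- if (phase == "entry") "down" else "up"

  mat <- kym$mat
  if (invert) mat <- -mat
  r <- kym$r_um
  if (!is.null(fold_at_um)) r <- abs(r - fold_at_um)

  tt <- rep(NA_real_, nrow(mat))
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    if (anyNA(v)) next
    rng <- max(v) - min(v)
    if (rng <= 0) next
    z <- (v - min(v)) / rng
    tt[i] <- crossing_time(z, kym$t_min, theta, dir, t_search_min)
  }

  ok <- !is.na(tt) & r > r_min_um
  if (!is.null(fold_at_um)) {
    # average the two arms onto common distance bins
    bw <- stats::median(diff(sort(unique(kym$r_um))))
    g <- round(r[ok] / bw)
    t_use <- tapply(tt[ok], g, mean)
    r_use <- as.numeric(names(t_use)) * bw
    t_use <- as.numeric(t_use)
  } else {
    o <- order(r[ok])
    r_use <- r[ok][o]; t_use <- tt[ok][o]
  }

  nofit <- structure(list(phase = phase, speed_um_per_min = NA_real_,
                          intercept_min = NA_real_, r_squared = NA_real_,
                          n_points = 0L,
                          front = tibble::tibble(r_um = numeric(), t_min = numeric()),
                          flagged = TRUE, reason = "fewer than 3 front points"),
                     class = "kymograph_fit")
  if (length(r_use) < 3) return(nofit)

  # monotone-advance window: stop where the front stalls. A stall must be
  # sustained (average increment over a two-step lookahead below the
  # threshold) so that a single noise-jittered crossing does not truncate
  # the fit.
  n_use <- length(r_use)
  stop_at <- n_use
  for (k in seq_len(n_use - 1)) {
    hi <- min(k + 2, n_use)
    if ((t_use[hi] - t_use[k]) <= stall_eps_min * (hi - k)) { stop_at <- k; break }
  }
  r_use <- r_use[seq_len(stop_at)]; t_use <- t_use[seq_len(stop_at)]
  if (length(r_use) < 3) return(nofit)

  fit <- lm(r_use ~ t_use)
  v <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  structure(list(phase = phase, speed_um_per_min = v,
                 intercept_min = unname(-coef(fit)[1] / coef(fit)[2]),
                 r_squared = r2, n_points = length(r_use),
                 front = tibble::tibble(r_um = r_use, t_min = t_use),
                 flagged = is.na(r2) || r2 < r2_flag || v <= 0,
                 reason = NA_character_),
            class = "kymograph_fit")
}

#' @export
print.kymograph_fit <- function(x, ...) {
  cat(sprintf("<kymograph_fit:%s> v = %.2f um/min, R2 = %.4f, n = %d%s\n",
              x$phase, x$speed_um_per_min, x$r_squared, x$n_points,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Average aligned kymographs
#'
#' Pointwise mean of event kymographs after aligning each event's t = 0 to
#' its source onset (the alignment is carried by each kymograph's own time
#' axis). Kymographs are resampled onto the coarsest common grid.
#'
#' @param kymographs Non-empty list of `kymograph` objects.
#' @return A `kymograph` of the mean.
#' @export
average_kymographs <- function(kymographs) {
  if (!length(kymographs)) stop("empty kymograph list")
  stopifnot(all(vapply(kymographs, inherits, TRUE, "kymograph")))
  dt <- max(vapply(kymographs, function(k) median(diff(k$t_min)), 1))
  dr <- max(vapply(kymographs, function(k) median(diff(k$r_um)), 1))
  t_lo <- max(vapply(kymographs, function(k) min(k$t_min), 1))
  t_hi <- min(vapply(kymographs, function(k) max(k$t_min), 1))
  r_lo <- max(vapply(kymographs, function(k) min(k$r_um), 1))
  r_hi <- min(vapply(kymographs, function(k) max(k$r_um), 1))
  stopifnot(t_hi > t_lo, r_hi >= r_lo)
  t_grid <- seq(t_lo, t_hi, by = dt)
  r_grid <- seq(r_lo, r_hi, by = dr)
  acc <- array(0, c(length(r_grid), length(t_grid)))
  for (k in kymographs) {
    # interpolate in time per original bin, then in r per target frame
    tmp <- matrix(NA_real_, length(k$r_um), length(t_grid))
    for (i in seq_along(k$r_um))
      tmp[i, ] <- stats::approx(k$t_min, k$mat[i, ], xout = t_grid, rule = 2)$y
    res <- matrix(NA_real_, length(r_grid), length(t_grid))
    for (j in seq_along(t_grid))
      res[, j] <- stats::approx(k$r_um, tmp[, j], xout = r_grid, rule = 2)$y
    acc <- acc + res
  }
  new_kymograph(acc / length(kymographs), r_grid, t_grid,
                origin = list(n_averaged = length(kymographs)),
                kind = kymographs[[1]]$kind)
}

#' Cycle-time advance of sources relative to the benchmark region
#'
#' For each source, the local cycle duration is the source onset in the
#' focal cycle minus the entry time at the source position in the previous
#' cycle; the benchmark duration is the mean entry-to-entry interval over
#' the benchmark mask. `delta_cycle_min = duration_benchmark -
#' duration_source`, so positive values mean the source cycles faster than
#' the slowest cytoplasm.
#'
#' @param sources Tibble from [extract_sources()] / [classify_sources()].
#' @param entry_prev,entry_cur [entry_time_map()]s of cycles c-1 and c.
#' @param benchmark Logical matrix from [benchmark_region()] (on cycle c).
#' @return `sources` with `duration_source_min`, `duration_benchmark_min`,
#'   `delta_cycle_min` and `percent` columns; sources without a defined
#'   previous onset are dropped (attribute `skipped` reports them).
#' @export
delta_cycle_times <- function(sources, entry_prev, entry_cur, benchmark) {
  stopifnot(inherits(entry_prev, "entry_time_map"),
            inherits(entry_cur, "entry_time_map"))
  if (!any(benchmark)) stop("benchmark mask is empty")
  both <- benchmark & !is.na(entry_prev$times) & !is.na(entry_cur$times)
  if (!any(both)) stop("benchmark has no pixels with entries in both cycles")
  dur_bench <- mean(entry_cur$times[both] - entry_prev$times[both])

  s <- entry_prev$pixel_size_um
  h <- nrow(entry_prev$times); w <- ncol(entry_prev$times)
  prev_at <- function(x_um, y_um) {
    cc <- min(max(ceiling(x_um / s), 1L), w)
    rr <- min(max(ceiling(y_um / s), 1L), h)
    v <- entry_prev$times[rr, cc]
    if (!is.na(v)) return(v)
    rr2 <- max(1, rr - 1):min(h, rr + 1)
    cc2 <- max(1, cc - 1):min(w, cc + 1)
    vv <- entry_prev$times[rr2, cc2]
    if (all(is.na(vv))) NA_real_ else mean(vv, na.rm = TRUE)
  }

  dur_src <- vapply(seq_len(nrow(sources)), function(i) {
    p <- prev_at(sources$x_um[i], sources$y_um[i])
    if (is.na(p)) NA_real_ else sources$onset_min[i] - p
  }, 1)
  keep <- !is.na(dur_src) & dur_src > 0
  skipped <- sources[!keep, , drop = FALSE]
  res <- sources[keep, , drop = FALSE]
  res$duration_source_min <- dur_src[keep]
  res$duration_benchmark_min <- dur_bench
  res$delta_cycle_min <- dur_bench - res$duration_source_min
  res$percent <- 100 * res$delta_cycle_min / dur_bench
  attr(res, "skipped") <- skipped
  res
}

#' Entry-time heat map
#'
#' Heat values are entry times relative to the earliest pixel of the cycle;
#' the benchmark (latest) region can be overlaid in green when plotting.
#'
#' @param entry_map An [entry_time_map()].
#' @param benchmark Optional logical matrix from [benchmark_region()].
#' @return An `entry_heatmap`: `rel_times` (min), `range_min`, `benchmark`.
#' @export
entry_heatmap <- function(entry_map, benchmark = NULL) {
  stopifnot(inherits(entry_map, "entry_time_map"))
  tm <- entry_map$times
  if (all(is.na(tm))) stop("entry map is empty")
  rel <- tm - min(tm, na.rm = TRUE)
  structure(list(rel_times = rel,
                 range_min = c(0, max(rel, na.rm = TRUE)),
                 benchmark = benchmark, cycle = entry_map$cycle,
                 pixel_size_um = entry_map$pixel_size_um),
            class = "entry_heatmap")
}

#' @export
plot.entry_heatmap <- function(x, ...) {
  pal <- grDevices::hcl.colors(64, "Inferno")
  graphics::image(t(x$rel_times)[, nrow(x$rel_times):1],
                  col = pal, axes = FALSE, asp = nrow(x$rel_times) / ncol(x$rel_times),
                  main = sprintf("cycle %d: relative entry time 0-%.0f min",
                                 x$cycle, x$range_min[2]), ...)
  if (!is.null(x$benchmark)) {
    bm <- x$benchmark
    bm[!bm] <- NA
    graphics::image(t(bm)[, nrow(bm):1], col = "#00aa00", add = TRUE)
  }
  invisible(x)
}
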