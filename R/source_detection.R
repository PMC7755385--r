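#' Source-detection parameters
#'
#' @param n_expand Number of frame-to-frame steps over which a candidate
#'   mitotic region must keep expanding. The trajectory is truncated at the
#'   frame where mitosis covers the whole well, so regions born shortly
#'   before a fast bulk entry are still assessable on the steps that exist;
#'   a region must show at least one strictly expanding step.
#' @param growth_min Minimum total relative area growth over the assessed
#'   steps.
#' @param concerted_frac When the regions appearing in the first occupied
#'   frame already cover at least this fraction of the valid area, the cycle
#'   is flagged "concerted" (a phase wave, not localised sources).
#' @param solidity_split First-frame regions with solidity below this and at
#'   least two distance-transform maxima are treated as dumbbells and split
#'   into two sources by watershed.
#' @param max_front_speed_um_per_min Cap on the apparent boundary speed
#'   (growth of the equivalent-circle radius per frame). Trigger waves
#'   expand at finite speed; concerted (phase-wave-like) entry of the
#'   surrounding bulk makes a region's area jump essentially instantaneously
#'   and terminates its assessable expansion.
#' @return A `source_params` object.
#' @export
source_params <- function(n_expand = 3, growth_min = 0.2,
                          concerted_frac = 0.9, solidity_split = 0.8,
                          max_front_speed_um_per_min = 300) {
  structure(list(n_expand = as.integer(n_expand), growth_min = growth_min,
                 concerted_frac = concerted_frac,
                 solidity_split = solidity_split,
                 max_front_speed_um_per_min = max_front_speed_um_per_min),
            class = "source_params")
}

# area of the convex hull of pixel centres (px^2), with a half-perimeter
# correction for rasterization
hull_area_px <- function(idx) {
  if (nrow(idx) < 3) return(nrow(idx))
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  xs <- idx[hull, 2]; ys <- idx[hull, 1]
  n <- length(xs)
  a <- abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
  per <- sum(sqrt(diff(c(xs, xs[1]))^2 + diff(c(ys, ys[1]))^2))
  a + per / 2 + 1
}

#' Detect expanding mitotic regions in an entry-time map
#'
#' Thresholds the entry-time map at successive frame times; connected
#' components are tracked from their first appearance, and a component is
#' retained as a mitotic region only if it expands from frame to frame
#' (microtubule-depleted areas that do not expand are not mitotic waves).
#'
#' @param entry_map An [entry_time_map()].
#' @param frame_interval Minutes per frame (defaults to the map's own).
#' @param params A [source_params()].
#' @return A `mitotic_regions` object: `regions` (retained), `rejected`
#'   (tibble with reasons), and a `concerted` flag.
#' @export
detect_mitotic_regions <- function(entry_map, frame_interval = NULL,
                                   params = source_params()) {
  stopifnot(inherits(entry_map, "entry_time_map"))
  if (is.null(frame_interval)) frame_interval <- entry_map$frame_interval_min
  tm <- entry_map$times
  h <- nrow(tm); w <- ncol(tm)
  valid <- !is.na(tm)
  n_valid <- sum(valid)
  empty <- structure(list(regions = list(),
                          rejected = tibble::tibble(id = integer(), reason = character()),
                          concerted = FALSE, cycle = entry_map$cycle,
                          pixel_size_um = entry_map$pixel_size_um),
                     class = "mitotic_regions")
  if (n_valid == 0) return(empty)

  f_lo <- floor(min(tm, na.rm = TRUE) / frame_interval)
  f_hi <- ceiling(max(tm, na.rm = TRUE) / frame_interval)
  regions <- list()
  sat_frame <- NA_integer_
  first_occupied <- NA_integer_
  concerted <- FALSE

  for (f in f_lo:f_hi) {
    B <- !is.na(tm) & tm <= f * frame_interval
    nb <- sum(B)
    if (nb == 0) next
    lab <- EBImage::bwlabel(B)
    if (is.na(first_occupied)) {
      first_occupied <- f
      if (nb >= params$concerted_frac * n_valid) concerted <- TRUE
    }
    if (is.na(sat_frame) && nb == n_valid) sat_frame <- f
    # grow existing regions
    for (ri in seq_along(regions)) {
      r <- regions[[ri]]
      l <- lab[r$seed[1]]
      regions[[ri]]$areas <- c(r$areas, sum(lab == l))
    }
    # births: components containing no existing seed
    seeds <- unlist(lapply(regions, function(r) r$seed[1]))
    taken <- if (length(seeds)) unique(lab[seeds]) else integer()
    for (l in setdiff(seq_len(max(lab)), taken)) {
      comp <- which(lab == l)
      if (!length(comp)) next
      rr <- ((comp - 1) %% h) + 1
      cc <- ((comp - 1) %/% h) + 1
      regions[[length(regions) + 1L]] <- list(
        id = length(regions) + 1L, f0 = f, seed = comp,
        first_mask_idx = cbind(row = rr, col = cc),
        onset_min = min(tm[comp]),
        centroid_um = c(x = mean((cc - 0.5) * entry_map$pixel_size_um),
                        y = mean((rr - 0.5) * entry_map$pixel_size_um)),
        areas = sum(lab == l))
    }
    if (!is.na(sat_frame) && f >= sat_frame) break
  }

  kept <- list(); rejected <- list()
  s_um <- entry_map$pixel_size_um
  for (r in regions) {
    # assessable expansion: strictly growing steps whose equivalent-radius
    # speed stays below the phase-wave cap (a jump marks concerted entry of
    # the surroundings or a wave merger)
    a <- r$areas
    r_eq <- s_um * sqrt(a / pi)
    n_ok <- 0L
    for (k in seq_len(length(a) - 1L)) {
      if (a[k + 1] <= a[k]) break
      if ((r_eq[k + 1] - r_eq[k]) / frame_interval >
          params$max_front_speed_um_per_min) break
      n_ok <- k
    }
    if (n_ok < 1L) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        id = r$id, reason = "no finite-speed expansion")
      next
    }
    m <- min(params$n_expand, n_ok)
    if ((a[m + 1] - a[1]) / a[1] < params$growth_min) {
      rejected[[length(rejected) + 1L]] <- data.frame(
        id = r$id, reason = "growth below threshold")
      next
    }
    kept[[length(kept) + 1L]] <- r
  }
  if (concerted) kept <- list()

  structure(list(regions = kept,
                 rejected = if (length(rejected)) tibble::as_tibble(do.call(rbind, rejected))
                            else tibble::tibble(id = integer(), reason = character()),
                 concerted = concerted, cycle = entry_map$cycle,
                 pixel_size_um = entry_map$pixel_size_um,
                 dims = c(h, w)),
            class = "mitotic_regions")
}

#' @export
print.mitotic_regions <- function(x, ...) {
  cat(sprintf("<mitotic_regions> cycle %d: %d retained, %d rejected%s\n",
              x$cycle, length(x$regions), nrow(x$rejected),
              if (x$concerted) " (concerted entry)" else ""))
  invisible(x)
}

#' Extract trigger-wave sources from mitotic regions
#'
#' The source of each retained region is the centroid of its first-frame
#' mask, with onset equal to the earliest entry time inside the region.
#' Dumbbell-shaped first frames (low solidity, two distance-transform
#' maxima) are split by watershed into two simultaneous sources placed at
#' the distance-transform maxima of the two largest basins, reflecting
#' mitoses that initiated nearly simultaneously from two adjacent structures.
#'
#' @param regions A `mitotic_regions` object.
#' @param params A [source_params()].
#' @return Tibble of sources: `region_id`, `cycle`, `x_um`, `y_um`,
#'   `onset_min`, `split`.
#' @export
extract_sources <- function(regions, params = source_params()) {
  stopifnot(inherits(regions, "mitotic_regions"))
  s <- regions$pixel_size_um
  out <- list()
  for (r in regions$regions) {
    idx <- r$first_mask_idx
    split <- FALSE
    if (nrow(idx) >= 8) {
      solidity <- nrow(idx) / hull_area_px(idx)
      if (solidity < params$solidity_split) {
        sub <- matrix(0, max(idx[, "row"]) - min(idx[, "row"]) + 3L,
                      max(idx[, "col"]) - min(idx[, "col"]) + 3L)
        sub[cbind(idx[, "row"] - min(idx[, "row"]) + 2L,
                  idx[, "col"] - min(idx[, "col"]) + 2L)] <- 1
        dm <- EBImage::distmap(sub)
        ws <- EBImage::watershed(dm, tolerance = 1)
        nb <- max(ws)
        if (nb >= 2) {
          sizes <- tabulate(ws[ws > 0], nb)
          top2 <- order(sizes, decreasing = TRUE)[1:2]
          for (b in top2) {
            bi <- which(ws == b)
            peak <- bi[which.max(dm[bi])]
            pr <- ((peak - 1) %% nrow(sub)) + 1 + min(idx[, "row"]) - 2L
            pc <- ((peak - 1) %/% nrow(sub)) + 1 + min(idx[, "col"]) - 2L
            out[[length(out) + 1L]] <- data.frame(
              region_id = r$id, cycle = regions$cycle,
              x_um = (pc - 0.5) * s, y_um = (pr - 0.5) * s,
              onset_min = r$onset_min, split = TRUE)
          }
          split <- TRUE
        }
      }
    }
    if (!split) {
      out[[length(out) + 1L]] <- data.frame(
        region_id = r$id, cycle = regions$cycle,
        x_um = r$centroid_um["x"], y_um = r$centroid_um["y"],
        onset_min = r$onset_min, split = FALSE)
    }
  }
  if (!length(out))
    return(tibble::tibble(region_id = integer(), cycle = integer(),
                          x_um = numeric(), y_um = numeric(),
                          onset_min = numeric(), split = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  tibble::as_tibble(res)
}

#' Classification parameters
#' @param proximity_radius_um Sources closer than this to a nucleus (or
#'   centrosome) are attributed to that structure (default 100 um).
#' @param edge_band_um Sources closer than this to the well boundary are
#'   edge-associated (default 100 um, mirroring the proximity radius).
#' @return A `classification_params` object.
#' @export
classification_params <- function(proximity_radius_um = 100, edge_band_um = 100) {
  stopifnot(proximity_radius_um >= 0, edge_band_um >= 0)
  structure(list(proximity_radius_um = proximity_radius_um,
                 edge_band_um = edge_band_um),
            class = "classification_params")
}

#' Classify sources by the nearest structure
#'
#' Assigns each source the class `nucleus`, `centrosome`, `edge` or `other`
#' with precedence in that order: nucleus if the nearest same-cycle nucleus
#' is within the proximity radius, else centrosome, else edge if within the
#' edge band of the well boundary. All three distances are stored regardless
#' of the class.
#'
#' @param sources Tibble from [extract_sources()].
#' @param nuclei Tibble from [detect_nuclei()] (may be empty); only nuclei
#'   of the source's cycle are considered.
#' @param centrosomes Two-column matrix/data frame of (x_um, y_um) positions,
#'   or `NULL`.
#' @param geometry A [well_geometry()].
#' @param params A [classification_params()].
#' @return `sources` with columns `class`, `d_nucleus_um`, `d_centrosome_um`,
#'   `d_edge_um` added.
#' @export
classify_sources <- function(sources, nuclei = NULL, centrosomes = NULL,
                             geometry, params = classification_params()) {
  n <- nrow(sources)
  d_nuc <- rep(Inf, n); d_cen <- rep(Inf, n); d_edge <- rep(Inf, n)
  bd <- boundary_distance_um(geometry)
  cen <- if (!is.null(centrosomes) && NROW(centrosomes) > 0)
    as.matrix(as.data.frame(centrosomes))[, 1:2, drop = FALSE] else NULL
  for (i in seq_len(n)) {
    if (!is.null(nuclei) && nrow(nuclei) > 0) {
      nu <- nuclei[!is.na(nuclei$cycle) & nuclei$cycle == sources$cycle[i], ]
      if (nrow(nu) > 0)
        d_nuc[i] <- min(sqrt((nu$x_um - sources$x_um[i])^2 +
                               (nu$y_um - sources$y_um[i])^2))
    }
    if (!is.null(cen))
      d_cen[i] <- min(sqrt((cen[, 1] - sources$x_um[i])^2 +
                             (cen[, 2] - sources$y_um[i])^2))
    px <- um_to_pixel(geometry, sources$x_um[i], sources$y_um[i])
    d_edge[i] <- bd[px[1, "row"], px[1, "col"]]
    if (is.na(d_edge[i])) d_edge[i] <- 0
  }
  cls <- ifelse(d_nuc < params$proximity_radius_um, "nucleus",
         ifelse(d_cen < params$proximity_radius_um, "centrosome",
         ifelse(d_edge < params$edge_band_um, "edge", "other")))
  sources$class <- cls
  sources$d_nucleus_um <- d_nuc
  sources$d_centrosome_um <- d_cen
  sources$d_edge_um <- d_edge
  sources
}

#' Benchmark region: the latest fraction of the well to enter mitosis
#'
#' The slowest-entering cytoplasm serves as the unentrained reference
#' against which source cycle times are compared. Ties at the cutoff time
#' are all included.
#'
#' @param entry_map An [entry_time_map()].
#' @param fraction Fraction of valid pixels (default 0.15).
#' @return Logical matrix, `TRUE` on the benchmark region.
#' @export
benchmark_region <- function(entry_map, fraction = 0.15) {
  stopifnot(inherits(entry_map, "entry_time_map"), fraction > 0, fraction <= 1)
  tm <- entry_map$times
  valid <- !is.na(tm)
  n <- sum(valid)
  if (n == 0) stop("entry map has no defined entries")
  if (n < 1 / fraction) stop("too few valid pixels for the requested fraction")
  thr <- quantile(tm[valid], 1 - fraction, names = FALSE)
  res <- !is.na(tm) & tm >= thr
  res
}
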