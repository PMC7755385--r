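#' Spatial bootstrap of source-structure proximity
#'
#' Tests whether more sources lie within `radius_um` of a reference
#' structure (nuclei or centrosomes) than expected by chance. Source
#' positions are randomised uniformly over the valid well pixels; the
#' p-value is the fraction of iterations with at least as many proximal
#' sources as observed.
#'
#' @param sources Tibble with `x_um`, `y_um` (one cycle's sources).
#' @param reference_points Two-column matrix/data frame of (x_um, y_um), or
#'   `NULL`/empty (gives observed count 0 and p = 1).
#' @param geometry A [well_geometry()].
#' @param radius_um Proximity radius (default 100 um).
#' @param n_iter Number of randomisations (default 1e5).
#' @param seed RNG seed.
#' @return A `bootstrap_result`: `observed_count`, `n_sources`, `n_iter`,
#'   `null_mean`, `null_counts` (histogram table), `p_value`, and
#'   `p_value_label` (reported as "< 1/n_iter" when no null iteration
#'   reaches the observed count).
#' @export
bootstrap_proximity_pvalue <- function(sources, reference_points, geometry,
                                       radius_um = 100, n_iter = 1e5,
                                       seed = 1L) {
  stopifnot(nrow(sources) >= 1, any(geometry$mask))
  n_src <- nrow(sources)
  refs <- if (!is.null(reference_points) && NROW(reference_points) > 0)
    as.matrix(as.data.frame(reference_points))[, 1:2, drop = FALSE] else NULL
  if (is.null(refs)) {
    return(structure(list(observed_count = 0L, n_sources = n_src,
                          n_iter = as.integer(n_iter), null_mean = 0,
                          null_counts = table(integer()), p_value = 1,
                          p_value_label = "1", radius_um = radius_um),
                     class = "bootstrap_result"))
  }
  near <- function(x, y) {
    d2min <- rep(Inf, length(x))
    for (k in seq_len(nrow(refs)))
      d2min <- pmin(d2min, (x - refs[k, 1])^2 + (y - refs[k, 2])^2)
    d2min < radius_um^2
  }
  observed <- sum(near(sources$x_um, sources$y_um))

  s <- geometry$pixel_size_um
  idx <- which(geometry$mask, arr.ind = TRUE)
  px_near <- near((idx[, "col"] - 0.5) * s, (idx[, "row"] - 0.5) * s)
  null_counts <- with_local_seed(seed, {
    draws <- matrix(sample(px_near, n_iter * n_src, replace = TRUE), nrow = n_iter)
    as.integer(rowSums(draws))
  })
  p <- sum(null_counts >= observed) / n_iter
  structure(list(observed_count = as.integer(observed), n_sources = n_src,
                 n_iter = as.integer(n_iter), null_mean = mean(null_counts),
                 null_counts = table(null_counts), p_value = p,
                 p_value_label = if (p == 0) sprintf("< %g", 1 / n_iter) else
                   format(p, digits = 4),
                 radius_um = radius_um),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d/%d sources within %g um; null mean %.2f; p = %s (%d iter)\n",
              x$observed_count, x$n_sources, x$radius_um, x$null_mean,
              x$p_value_label, x$n_iter))
  invisible(x)
}

#' Observed and mock nearest-structure distance distributions
#'
#' @param sources Tibble with `x_um`, `y_um`.
#' @param reference_points Two-column matrix/data frame of (x_um, y_um).
#' @param geometry A [well_geometry()].
#' @param n_mock Number of uniformly randomised source sets pooled into the
#'   mock distribution.
#' @param seed RNG seed.
#' @return List with `observed` and `mock` numeric vectors of
#'   nearest-reference distances (um).
#' @export
distance_distribution <- function(sources, reference_points, geometry,
                                  n_mock = 100, seed = 1L) {
  refs <- as.matrix(as.data.frame(reference_points))[, 1:2, drop = FALSE]
  stopifnot(nrow(refs) >= 1)
  nearest <- function(x, y) {
    d2 <- rep(Inf, length(x))
    for (k in seq_len(nrow(refs)))
      d2 <- pmin(d2, (x - refs[k, 1])^2 + (y - refs[k, 2])^2)
    sqrt(d2)
  }
  observed <- nearest(sources$x_um, sources$y_um)
  s <- geometry$pixel_size_um
  idx <- which(geometry$mask, arr.ind = TRUE)
  n_src <- nrow(sources)
  mock <- with_local_seed(seed, {
    pick <- sample(nrow(idx), n_mock * n_src, replace = TRUE)
    nearest((idx[pick, "col"] - 0.5) * s, (idx[pick, "row"] - 0.5) * s)
  })
  list(observed = observed, mock = mock)
}

#' Per-cycle class-fraction curves across experiments
#'
#' Within each experiment the per-cycle fraction of sources in each class is
#' computed; fractions are then averaged across experiments, with the SEM.
#' Cycles with no sources in an experiment are excluded from that cycle's
#' mean.
#'
#' @param sources Tibble of classified sources with columns `experiment`,
#'   `cycle`, `class`.
#' @param classes Class levels to tabulate.
#' @return Tibble (cycle, class, mean_fraction, sem, n_experiments,
#'   sem_defined). With a single experiment the SEM is reported as 0 and
#'   `sem_defined` is `FALSE`.
#' @export
class_fraction_curves <- function(sources,
                                  classes = c("nucleus", "centrosome", "edge", "other")) {
  stopifnot(all(c("experiment", "cycle", "class") %in% names(sources)),
            nrow(sources) >= 1)
  out <- list()
  for (cy in sort(unique(sources$cycle))) {
    sub <- sources[sources$cycle == cy, ]
    fr <- lapply(split(sub$class, sub$experiment), function(cl) {
      vapply(classes, function(k) mean(cl == k), 1)
    })
    m <- do.call(rbind, fr)
    ne <- nrow(m)
    for (k in classes) {
      v <- m[, k]
      out[[length(out) + 1L]] <- data.frame(
        cycle = cy, class = k, mean_fraction = mean(v),
        sem = if (ne > 1) sd(v) / sqrt(ne) else 0,
        n_experiments = ne, sem_defined = ne > 1)
    }
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Earliest-firing ("best") sources of a cycle
#'
#' @param sources Tibble with `onset_min` (one cycle).
#' @param fraction Fraction of sources to keep (default 0.10); at least one
#'   source is returned and ties at the cutoff are included.
#' @return Subset of `sources`.
#' @export
best_sources <- function(sources, fraction = 0.10) {
  stopifnot(nrow(sources) >= 1, fraction > 0, fraction <= 1)
  k <- max(1L, floor(fraction * nrow(sources)))
  cutoff <- sort(sources$onset_min)[k]
  sources[sources$onset_min <= cutoff, , drop = FALSE]
}
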