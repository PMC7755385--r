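#' Pacemaker locus
#'
#' A spatially localised region whose autonomous cell-cycle period is
#' shortened relative to the bulk cytoplasm. In the kinematic model a
#' pacemaker is a disk of radius `radius_um` within which every cycle is
#' shorter by `advance_min` minutes; the phase lead it accumulates launches
#' circular entry waves that entrain the surroundings.
#'
#' @param x_um,y_um Position in micrometres (must fall inside the well mask).
#' @param advance_min Per-cycle phase advance in minutes (>= 0, and less than
#'   the bulk period).
#' @param radius_um Radius of the advanced disk (default 30 um, the scale of
#'   a reconstituted nucleus).
#' @param kind Ground-truth bookkeeping label: `"nucleus"`, `"centrosome"`,
#'   `"edge"` or `"other"`.
#' @return A `pacemaker` object.
#' @export
pacemaker <- function(x_um, y_um, advance_min, radius_um = 30,
                      kind = c("nucleus", "centrosome", "edge", "other")) {
  kind <- match.arg(kind)
  stopifnot(advance_min >= 0, radius_um > 0)
  structure(list(x_um = x_um, y_um = y_um, advance_min = advance_min,
                 radius_um = radius_um, kind = kind),
            class = "pacemaker")
}

#' Oscillator field
#'
#' Parameters of the kinematic relaxation-oscillator field: a bulk autonomous
#' period, the time of the first (concerted) mitotic entry, pacemaker loci,
#' and the speeds of the mitotic-entry (microtubule depolymerization) and
#' mitotic-exit (aster regrowth) fronts.
#'
#' Mitotic exit is wave-borne: exit fronts are launched from each pacemaker
#' `mitosis_duration_min` minutes after the pacemaker enters mitosis and
#' travel at `v_exit_um_per_min`. Cytoplasm that no exit wave reaches leaves
#' mitosis autonomously after `mitosis_duration_bulk_min`. Because the exit
#' front is slower than the entry front, the mitotic band widens with
#' distance from a source, up to that autonomous cap.
#'
#' @param base_period_min Bulk autonomous period P (min).
#' @param phase0_min Time of first mitotic entry of the bulk (min). The first
#'   cycle is concerted: pacemaker advances act from cycle 2 onward, so
#'   cycle-c autonomous entry is `phase0 + (c - 1) * (P - advance)`.
#' @param pacemakers List of [pacemaker()] objects (may be empty).
#' @param v_entry_um_per_min Entry front speed (um/min, > 0).
#' @param v_exit_um_per_min Exit front speed (um/min, > 0, <= entry speed).
#' @param mitosis_duration_min Minutes from entry to exit-wave launch at a
#'   pacemaker (M).
#' @param mitosis_duration_bulk_min Autonomous mitosis duration of cytoplasm
#'   no exit wave reaches (must satisfy M <= bulk duration < P).
#' @return An `oscillator_field` object.
#' @export
oscillator_field <- function(base_period_min = 40, phase0_min = 10,
                             pacemakers = list(),
                             v_entry_um_per_min = 60, v_exit_um_per_min = 40,
                             mitosis_duration_min = 10,
                             mitosis_duration_bulk_min = 18) {
  stopifnot(v_entry_um_per_min > 0, v_exit_um_per_min > 0,
            mitosis_duration_min > 0,
            mitosis_duration_min < base_period_min,
            mitosis_duration_bulk_min >= mitosis_duration_min,
            mitosis_duration_bulk_min < base_period_min)
  if (v_exit_um_per_min > v_entry_um_per_min)
    stop("exit front speed must not exceed entry front speed")
  if (inherits(pacemakers, "pacemaker")) pacemakers <- list(pacemakers)
  for (pm in pacemakers) {
    if (!inherits(pm, "pacemaker")) stop("pacemakers must be pacemaker objects")
    if (pm$advance_min >= base_period_min)
      stop("pacemaker advance must be smaller than the base period")
  }
  structure(list(base_period_min = base_period_min, phase0_min = phase0_min,
                 pacemakers = pacemakers,
                 v_entry_um_per_min = v_entry_um_per_min,
                 v_exit_um_per_min = v_exit_um_per_min,
                 mitosis_duration_min = mitosis_duration_min,
                 mitosis_duration_bulk_min = mitosis_duration_bulk_min),
            class = "oscillator_field")
}

# per-pixel advance field (min): max advance over covering pacemaker disks
advance_field <- function(field, geometry) {
  co <- pixel_coords_um(geometry)
  a <- matrix(0, geometry$height_px, geometry$width_px)
  for (pm in field$pacemakers) {
    cov <- (co$x - pm$x_um)^2 + (co$y - pm$y_um)^2 <= pm$radius_um^2
    cov <- cov & geometry$mask
    a[cov] <- pmax(a[cov], pm$advance_min)
  }
  a[!geometry$mask] <- NA_real_
  a
}

#' Exact entry/exit-time maps of the kinematic wave model
#'
#' Computes, for every valid pixel and every cycle, the mitotic-entry time
#' \eqn{T_c(x)} and mitotic-exit time \eqn{E_c(x)} of the entrained
#' oscillator field. The autonomous schedule of a pixel y is
#' \eqn{\tau_c(y) = \mathrm{phase0} + \sum_{j<c} P_j(y)} with
#' \eqn{P_j(y) = P - a(y)} for local advance a(y); entrained entry is the
#' generalized distance transform
#' \eqn{T_c(x) = \min_y [\tau_c(y) + d(x,y)/v_\mathrm{entry}]}
#' over all valid pixels y (Euclidean distance; the well must be convex so
#' in-mask geodesics equal straight lines). Exit is the first arrival of an
#' exit wave launched from a pacemaker, capped by the autonomous bulk
#' mitosis duration.
#'
#' @param field An [oscillator_field()].
#' @param geometry A [well_geometry()] with a convex mask.
#' @param n_cycles Number of cycles (>= 1).
#' @return A `ground_truth` object: `entry_maps` and `exit_maps` are
#'   `height x width x n_cycles` arrays (min, `NA` outside the mask);
#'   `pacemaker_table` is a tibble of per-cycle firing times; `nucleus_truth`
#'   starts empty and can be filled by [simulate_nucleus_lineage()] or
#'   [simulate_well()].
#' @export
compute_entry_exit_maps <- function(field, geometry, n_cycles) {
  stopifnot(inherits(field, "oscillator_field"),
            inherits(geometry, "well_geometry"), n_cycles >= 1)
  n_cycles <- as.integer(n_cycles)
  if (!is_convex_mask(geometry))
    stop("kinematic generator requires a convex well mask")
  h <- geometry$height_px; w <- geometry$width_px
  s <- geometry$pixel_size_um
  mask <- geometry$mask
  co <- pixel_coords_um(geometry)
  for (pm in field$pacemakers) {
    px <- um_to_pixel(geometry, pm$x_um, pm$y_um)
    if (!mask[px[1, "row"], px[1, "col"]])
      stop("pacemaker position outside the well mask")
  }

  a <- advance_field(field, geometry)
  vals <- sort(unique(a[mask & a > 0]))
  # distance (um) from every pixel to the nearest pixel of each advance class
  dist_to_set_um <- function(set) {
    idx <- which(set)
    d2 <- matrix(Inf, h, w)
    sx <- co$x[idx]; sy <- co$y[idx]
    for (k in seq_along(idx)) {
      d2 <- pmin(d2, (co$x - sx[k])^2 + (co$y - sy[k])^2)
    }
    sqrt(d2)
  }
  class_dist <- lapply(vals, function(v) dist_to_set_um(a == v & mask))

  P <- field$base_period_min
  v_in <- field$v_entry_um_per_min
  v_out <- field$v_exit_um_per_min
  M <- field$mitosis_duration_min
  Mb <- field$mitosis_duration_bulk_min

  entry <- array(NA_real_, c(h, w, n_cycles))
  exitm <- array(NA_real_, c(h, w, n_cycles))
  pm_rows <- lapply(field$pacemakers, function(pm) um_to_pixel(geometry, pm$x_um, pm$y_um))
  pm_dist <- lapply(field$pacemakers, function(pm)
    sqrt((co$x - pm$x_um)^2 + (co$y - pm$y_um)^2))

  fire <- vector("list", length(field$pacemakers))
  for (c_i in seq_len(n_cycles)) {
    Tc <- matrix(field$phase0_min + (c_i - 1) * P, h, w)
    for (g in seq_along(vals)) {
      tau_g <- field$phase0_min + (c_i - 1) * (P - vals[g])
      Tc <- pmin(Tc, tau_g + class_dist[[g]] / v_in)
    }
    Ec <- Tc + Mb
    for (k in seq_along(field$pacemakers)) {
      px <- pm_rows[[k]]
      t_fire <- Tc[px[1, "row"], px[1, "col"]]
      fire[[k]] <- c(fire[[k]], t_fire)
      Ec <- pmin(Ec, t_fire + M + pm_dist[[k]] / v_out)
    }
    Tc[!mask] <- NA_real_
    Ec[!mask] <- NA_real_
    entry[, , c_i] <- Tc
    exitm[, , c_i] <- Ec
  }

  pm_tab <- if (length(field$pacemakers)) {
    tibble::tibble(
      id = seq_along(field$pacemakers),
      x_um = vapply(field$pacemakers, `[[`, numeric(1), "x_um"),
      y_um = vapply(field$pacemakers, `[[`, numeric(1), "y_um"),
      advance_min = vapply(field$pacemakers, `[[`, numeric(1), "advance_min"),
      radius_um = vapply(field$pacemakers, `[[`, numeric(1), "radius_um"),
      kind = vapply(field$pacemakers, `[[`, character(1), "kind"),
      firing_times_min = lapply(fire, identity)
    )
  } else {
    tibble::tibble(id = integer(), x_um = numeric(), y_um = numeric(),
                   advance_min = numeric(), radius_um = numeric(),
                   kind = character(), firing_times_min = list())
  }

  structure(list(entry_maps = entry, exit_maps = exitm,
                 pacemaker_table = pm_tab,
                 nucleus_truth = tibble::tibble(cycle = integer(), id = integer(),
                                                x_um = numeric(), y_um = numeric()),
                 n_cycles = n_cycles),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d cycle(s), %d pacemaker(s), %d nuclei rows\n",
              x$n_cycles, nrow(x$pacemaker_table), nrow(x$nucleus_truth)))
  invisible(x)
}
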