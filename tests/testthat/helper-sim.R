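# shared fixture builders (all synthetic, generated at test time)

# brute-force entry-time oracle: double loop over all pixel pairs
oracle_entry_maps <- function(field, geometry, n_cycles) {
  h <- geometry$height_px; w <- geometry$width_px; s <- geometry$pixel_size_um
  cx <- matrix(rep((seq_len(w) - 0.5) * s, each = h), h, w)
  cy <- matrix(rep((seq_len(h) - 0.5) * s, w), h, w)
  a <- matrix(0, h, w)
  for (pm in field$pacemakers) {
    sel <- (cx - pm$x_um)^2 + (cy - pm$y_um)^2 <= pm$radius_um^2
    a[sel] <- pmax(a[sel], pm$advance_min)
  }
  out <- array(NA_real_, c(h, w, n_cycles))
  for (ci in seq_len(n_cycles)) {
    tau <- field$phase0_min + (ci - 1) * (field$base_period_min - a)
    Tb <- matrix(Inf, h, w)
    for (i in seq_len(h * w)) {
      d <- sqrt((cx - cx[i])^2 + (cy - cy[i])^2)
      Tb <- pmin(Tb, tau[i] + d / field$v_entry_um_per_min)
    }
    out[, , ci] <- Tb
  }
  out
}

# single-pacemaker well tuned for front-speed measurements: the advance is
# matched to the entry speed so the entrained radius covers the fit range
sim_speed_well <- function(v_entry, v_exit, noise_frac = 0, seed = 1,
                           side_mm = 1.6, pixel_size_um = 6.5,
                           frame_interval_min = 2) {
  centre <- side_mm * 1000 / 2
  adv <- min(24, max(6, 470 / v_entry))
  pmt <- tibble::tibble(x_um = centre, y_um = centre, advance_min = adv,
                        kind = "nucleus")
  simulate_well(side_mm = side_mm, pixel_size_um = pixel_size_um,
                pacemakers = pmt, n_cycles = 2, base_period_min = 40,
                phase0_min = 4, v_entry = v_entry, v_exit = v_exit,
                mitosis_min = 10, mitosis_bulk_min = 26,
                frame_interval_min = frame_interval_min,
                noise_frac = noise_frac, seed = seed)
}

fit_event_speeds <- function(sim, r_max_um = 430, bin_width_um = 13) {
  centre <- c(sim$field$pacemakers[[1]]$x_um, sim$field$pacemakers[[1]]$y_um)
  onset <- sim$truth$pacemaker_table$firing_times_min[[1]][2]
  ky <- radial_kymograph(sim$movie, centre, r_max_um = r_max_um,
                         bin_width_um = bin_width_um,
                         geometry = sim$geometry, t0_min = onset)
  list(entry = fit_front_speed(ky, "entry", r_min_um = 40, t_search_min = -4),
       exit = fit_front_speed(ky, "exit", r_min_um = 40, t_search_min = -4))
}

# small multi-pacemaker well for pipeline recovery tests
sim_pipeline_well <- function(advances, kinds = rep("nucleus", length(advances)),
                              noise_frac = 0.1, seed = 1, side_mm = 2.6,
                              pixel_size_um = 13, frame_interval_min = 2,
                              base_period_min = 40) {
  side <- side_mm * 1000
  pos <- list(c(0.28, 0.3), c(0.72, 0.68), c(0.3, 0.72), c(0.72, 0.28))
  stopifnot(length(advances) <= 4)
  pmt <- tibble::tibble(
    x_um = vapply(pos[seq_along(advances)], function(p) p[1] * side, 1),
    y_um = vapply(pos[seq_along(advances)], function(p) p[2] * side, 1),
    advance_min = advances, kind = kinds)
  simulate_well(side_mm = side_mm, pixel_size_um = pixel_size_um,
                pacemakers = pmt, n_cycles = 2,
                base_period_min = base_period_min, phase0_min = 10,
                frame_interval_min = frame_interval_min,
                noise_frac = noise_frac, seed = seed)
}
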