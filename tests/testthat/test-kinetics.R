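make_map <- function(times, pixel_size_um = 13, frame_interval_min = 2, cycle = 2L) {
  structure(list(times = times, cycle = cycle, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min),
            class = "entry_time_map")
}

test_that("delta-cycle time follows the benchmark-minus-source convention", {
  h <- 40; w <- 40
  prev <- make_map(matrix(10, h, w), cycle = 1L)
  cur_t <- matrix(50.5, h, w)
  cur <- make_map(cur_t)
  bench <- matrix(FALSE, h, w); bench[, 35:40] <- TRUE
  src <- tibble::tibble(region_id = 1L, cycle = 2L, x_um = 130, y_um = 130,
                        onset_min = 40.4, split = FALSE)
  res <- delta_cycle_times(src, prev, cur, bench)
  expect_equal(res$duration_source_min, 30.4)
  expect_equal(res$duration_benchmark_min, 40.5)
  expect_equal(res$delta_cycle_min, 10.1)
  expect_equal(res$percent, 100 * 10.1 / 40.5, tolerance = 1e-9)

  src0 <- src; src0$onset_min <- 50.5
  expect_equal(delta_cycle_times(src0, prev, cur, bench)$delta_cycle_min, 0)

  expect_error(delta_cycle_times(src, prev, cur, matrix(FALSE, h, w)),
               "benchmark mask is empty")
})

test_that("the pipeline recovers a planted advance within one frame", {
  sim <- sim_pipeline_well(advances = 8, noise_frac = 0)
  ana <- analyze_well(sim$movie, cycle = 2, geometry = sim$geometry)
  nuc <- ana$sources[ana$sources$class == "nucleus", ]
  expect_equal(nrow(nuc), 1)
  expect_lt(abs(nuc$delta_cycle_min - 8), sim$movie$frame_interval_min)
})

test_that("linear kymographs have the declared geometry", {
  g <- well_geometry(60, 60, 10)
  arr <- array(100, c(60, 60, 5))
  mv <- movie(list(tubulin = arr), 10, 2)
  ky <- linear_kymograph(mv, c(50, 300), c(455, 300), bin_width_um = 13)
  expect_equal(nrow(ky$mat), ceiling(405 / 13))
  expect_true(all(ky$mat == 100))  # constant movie, constant kymograph
  expect_error(linear_kymograph(mv, c(50, 300), c(1200, 300),
                                geometry = well_geometry(60, 60, 10, shape = "disk")),
               "outside the well mask")
})

test_that("front speeds are recovered from linear and radial kymographs", {
  sim <- sim_speed_well(65, 40)
  fits <- fit_event_speeds(sim)
  expect_lt(abs(fits$entry$speed_um_per_min - 65) / 65, 0.02)
  expect_lt(abs(fits$exit$speed_um_per_min - 40) / 40, 0.02)
  expect_gt(fits$entry$r_squared, 0.99)

  onset <- sim$truth$pacemaker_table$firing_times_min[[1]][2]
  kl <- linear_kymograph(sim$movie, c(20, 800), c(1580, 800), width_px = 3,
                         geometry = sim$geometry, t0_min = onset)
  fl_in <- fit_front_speed(kl, "entry", r_min_um = 40, t_search_min = -4,
                           fold_at_um = 780)
  fl_out <- fit_front_speed(kl, "exit", r_min_um = 40, t_search_min = -4,
                            fold_at_um = 780)
  expect_lt(abs(fl_in$speed_um_per_min - 65) / 65, 0.02)
  expect_lt(abs(fl_out$speed_um_per_min - 40) / 40, 0.02)
})

test_that("fitted speed is insensitive to the frame interval", {
  sim2 <- sim_speed_well(60, 35, frame_interval_min = 2)
  sim4 <- sim_speed_well(60, 35, frame_interval_min = 4)
  v2 <- fit_event_speeds(sim2)$entry$speed_um_per_min
  v4 <- fit_event_speeds(sim4)$entry$speed_um_per_min
  expect_lt(abs(v4 - v2) / v2, 0.05)
})

test_that("radial kymograph of a circular wave matches the linear profile", {
  sim <- sim_speed_well(60, 40)
  onset <- sim$truth$pacemaker_table$firing_times_min[[1]][2]
  ky_r <- radial_kymograph(sim$movie, c(800, 800), r_max_um = 400,
                           bin_width_um = 13, geometry = sim$geometry,
                           t0_min = onset)
  ky_l <- linear_kymograph(sim$movie, c(800, 800), c(1240, 800), width_px = 1,
                           bin_width_um = 13, geometry = sim$geometry,
                           t0_min = onset)
  n <- nrow(ky_r$mat)
  rng <- max(ky_l$mat) - min(ky_l$mat)
  expect_lt(max(abs(ky_r$mat - ky_l$mat[seq_len(n), ])) / rng, 0.05)
})

test_that("averaging kymographs reduces noise like sqrt(n)", {
  set.seed(21)
  base <- outer(seq_len(30), seq_len(40), function(i, j) 100 + 5 * i + j)
  mk <- function() wavepace:::new_kymograph(base + rnorm(length(base), sd = 8),
                                            seq_len(30) * 13, seq_len(40) * 2,
                                            list(), "radial")
  one <- mk()
  expect_equal(average_kymographs(list(one, one))$mat, one$mat)

  kyms <- replicate(33, mk(), simplify = FALSE)
  avg <- average_kymographs(kyms)
  sd_avg <- sd(avg$mat - base)
  expect_lt(abs(sd_avg - 8 / sqrt(33)) / (8 / sqrt(33)), 0.2)
})

test_that("averaged-kymograph fits track the per-event mean with a quantile bias", {
  # analytic wave kymographs: intensity drops as the front passes r = v t.
  # The threshold crossing of a pointwise-averaged kymograph sits at a
  # quantile of the event arrival times, so the fitted speed exceeds the
  # per-event mean by an amount that grows with the speed spread and
  # vanishes as the spread shrinks.
  set.seed(33)
  r <- seq(26, 600, by = 13); tt <- seq(-6, 20, by = 2)
  bias_at_cv <- function(cv) {
    z <- rnorm(33); z <- (z - mean(z)) / sd(z)
    kyms <- lapply(54 * (1 + cv * z), function(v) {
      mat <- outer(r, tt, function(r, t) 200 - 120 / (1 + exp(-(t - r / v))))
      wavepace:::new_kymograph(mat, r, tt, list(), "radial")
    })
    per_event <- vapply(kyms, function(k)
      fit_front_speed(k, "entry")$speed_um_per_min, 1)
    v_avg <- fit_front_speed(average_kymographs(kyms), "entry")$speed_um_per_min
    (v_avg - mean(per_event)) / mean(per_event)
  }
  b25 <- bias_at_cv(0.25); b10 <- bias_at_cv(0.10)
  expect_gt(b25, 0)              # biased toward the faster events
  expect_lt(b25, 0.10)
  expect_lt(abs(b10), 0.02)      # negligible for tight ensembles
})

test_that("entry heat maps are relative to the earliest pixel", {
  hm_u <- entry_heatmap(make_map(matrix(25, 10, 10)))
  expect_true(all(hm_u$rel_times == 0))

  tm <- matrix(runif(100, 46, 64), 10, 10)
  tm[1] <- 46; tm[100] <- 64
  hm <- entry_heatmap(make_map(tm))
  expect_equal(hm$range_min, c(0, 18))
  hm_shift <- entry_heatmap(make_map(tm + 7))
  expect_equal(hm_shift$rel_times, hm$rel_times)
})
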