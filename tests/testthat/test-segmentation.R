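test_that("well mask recovers the generating geometry and ignores scaling", {
  g <- well_geometry(100, 100, 13, shape = "disk")
  f <- oscillator_field(phase0_min = 15)
  tr <- compute_entry_exit_maps(f, g, 1)
  mv <- render_movie(tr, f, g, render_config(noise_sd = 8, seed = 2,
                                             duration_min = 40))
  gm <- make_well_mask(mv)
  iou <- sum(gm$mask & g$mask) / sum(gm$mask | g$mask)
  expect_gte(iou, 0.98)

  mv10 <- mv; mv10$channels$tubulin <- mv10$channels$tubulin * 10
  expect_identical(make_well_mask(mv10)$mask, gm$mask)

  dark <- movie(list(tubulin = array(0, c(8, 8, 3))), 10, 1)
  expect_error(make_well_mask(dark), "empty mask")
})

test_that("cycle decomposition counts complete oscillations", {
  # 40-min period sampled each minute over 400 min: the final mitosis has no
  # interphase recovery inside the trace, leaving 9 complete cycles
  tr <- sin(2 * pi * (0:400) / 40)
  cyc <- decompose_cycles(tr, 1, segmentation_params(smooth_window = 1))
  expect_equal(sum(cyc$complete), 9)

  # extended recording: 14 complete mitotic cycles
  tr14 <- sin(2 * pi * (0:570) / 40)
  c14 <- decompose_cycles(tr14, 1, segmentation_params(smooth_window = 1))
  expect_equal(nrow(c14), 14)
  expect_true(all(c14$complete))
  expect_true(all(diff(c14$entry_min) > 0))
})

test_that("entry times interpolate the normalised threshold crossing", {
  # cycle spans 300 -> 100; 0.75 of the range is 250, crossed a quarter of
  # the way through the 300 -> 100 drop
  tr <- c(300, 300, 300, 100, 100, 100, 300, 300)
  cyc <- decompose_cycles(tr, 2, segmentation_params(smooth_window = 1))
  expect_equal(cyc$entry_min, 4.5)

  # invariance to intensity offset, equivariance to time shift
  cyc_off <- decompose_cycles(tr + 500, 2, segmentation_params(smooth_window = 1))
  expect_equal(cyc_off$entry_min, cyc$entry_min)
  cyc_shift <- decompose_cycles(c(300, 300, tr), 2,
                                segmentation_params(smooth_window = 1))
  expect_equal(cyc_shift$entry_min, cyc$entry_min + 2 * 2)

  # flat trace: no cycles
  expect_equal(nrow(decompose_cycles(rep(100, 50), 1)), 0)
})

test_that("planted nuclei are detected at their positions and cycle", {
  set.seed(7)
  g_side <- 1.3
  xs <- rep(c(260, 520, 780, 1040), 3)
  ys <- rep(c(330, 650, 970), each = 4)
  sim <- simulate_well(side_mm = g_side, pixel_size_um = 13, pacemakers = NULL,
                       n_cycles = 2, phase0_min = 10, noise_frac = 0.05, seed = 3)
  sim$truth$nucleus_truth <- tibble::tibble(cycle = 2L, id = 1:12,
                                            x_um = xs, y_um = ys)
  rc <- render_config(frame_interval_min = 2, noise_sd = 6, seed = 3)
  mv <- render_movie(sim$truth, sim$field, sim$geometry, rc)
  series <- segment_movie(mv, sim$geometry)
  nuc <- detect_nuclei(mv, series)
  expect_equal(nrow(nuc), 12)
  expect_true(all(nuc$cycle == 2))
  d <- vapply(seq_len(12), function(i)
    min(sqrt((nuc$x_um - xs[i])^2 + (nuc$y_um - ys[i])^2)), 1)
  expect_true(all(d <= 2 * 13))
})

test_that("a pure-noise NLS channel yields no nucleus detections", {
  sim <- simulate_well(side_mm = 1.0, pixel_size_um = 13, pacemakers = NULL,
                       n_cycles = 2, phase0_min = 10, noise_frac = 0.05, seed = 4)
  mv <- sim$movie
  set.seed(11)
  mv$channels$nls <- array(rnorm(length(mv$channels$nls), sd = 6),
                           dim(mv$channels$nls))
  series <- segment_movie(mv, sim$geometry)
  nuc <- detect_nuclei(mv, series)
  expect_equal(nrow(nuc), 0)
})

test_that("nucleus fold change is the geometric mean ratio", {
  expect_equal(nucleus_fold_change(c(4, 7, 12, 20)), 5^(1 / 3))
})
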