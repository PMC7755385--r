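test_that("entry maps match the brute-force generalized distance transform", {
  g <- well_geometry(48, 48, 10)
  pms <- list(pacemaker(120, 150, 12, radius_um = 25, kind = "nucleus"),
              pacemaker(350, 330, 7, radius_um = 25, kind = "other"))
  f <- oscillator_field(40, 30, pms, v_entry_um_per_min = 60)
  tr <- compute_entry_exit_maps(f, g, 3)
  oracle <- oracle_entry_maps(f, g, 3)
  for (ci in 1:3)
    expect_identical(tr$entry_maps[, , ci], oracle[, , ci])
})

test_that("with no pacemakers the field is a pure phase wave", {
  g <- well_geometry(20, 20, 10)
  f <- oscillator_field(40, 30, list())
  tr <- compute_entry_exit_maps(f, g, 2)
  expect_true(all(tr$entry_maps[, , 1] == 30))
  expect_true(all(tr$entry_maps[, , 2] == 70))
})

test_that("a pixel inside the entrained radius enters d/v after the pacemaker", {
  # point-like pacemaker (disk smaller than a pixel) at a pixel centre
  g <- well_geometry(11, 81, 10)
  f <- oscillator_field(40, 30, list(pacemaker(105, 55, 15, radius_um = 4)),
                        v_entry_um_per_min = 60)
  tr <- compute_entry_exit_maps(f, g, 2)
  t_pm <- tr$entry_maps[6, 11, 2]
  # pixel 600 um along the row: 600/60 = 10 min behind, within the 15-min lead
  expect_equal(tr$entry_maps[6, 71, 2], t_pm + 10)
})

test_that("entry maps are Lipschitz with constant 1/v_entry", {
  g <- well_geometry(32, 32, 10)
  f <- oscillator_field(40, 30, list(pacemaker(100, 100, 14, radius_um = 30)),
                        v_entry_um_per_min = 50)
  tr <- compute_entry_exit_maps(f, g, 2)
  co <- wavepace:::pixel_coords_um(g)
  set.seed(42)
  i <- sample(length(co$x), 300, replace = TRUE)
  j <- sample(length(co$x), 300, replace = TRUE)
  for (ci in 1:2) {
    Tm <- tr$entry_maps[, , ci]
    d <- sqrt((co$x[i] - co$x[j])^2 + (co$y[i] - co$y[j])^2)
    expect_true(all(abs(Tm[i] - Tm[j]) <= d / 50 + 1e-9))
  }
})

test_that("entrainment is monotone in pacemakers and in entry speed", {
  g <- well_geometry(30, 30, 10)
  base <- oscillator_field(40, 30, list(pacemaker(80, 80, 10, radius_um = 25)))
  more <- oscillator_field(40, 30, list(pacemaker(80, 80, 10, radius_um = 25),
                                        pacemaker(220, 220, 8, radius_um = 25)))
  t1 <- compute_entry_exit_maps(base, g, 2)
  t2 <- compute_entry_exit_maps(more, g, 2)
  expect_true(all(t2$entry_maps <= t1$entry_maps + 1e-12))

  faster <- base; faster$v_entry_um_per_min <- 80
  t3 <- compute_entry_exit_maps(faster, g, 2)
  expect_true(all(t3$entry_maps <= t1$entry_maps + 1e-12))
})

test_that("exit maps respect the wave-borne exit model", {
  g <- well_geometry(11, 81, 10)
  f <- oscillator_field(40, 30, list(pacemaker(105, 55, 15, radius_um = 4)),
                        v_entry_um_per_min = 60, v_exit_um_per_min = 40,
                        mitosis_duration_min = 10, mitosis_duration_bulk_min = 18)
  tr <- compute_entry_exit_maps(f, g, 2)
  expect_true(all(tr$exit_maps > tr$entry_maps))
  t_pm <- tr$entry_maps[6, 11, 2]
  # 300 um out: exit wave (10 + 300/40 = 17.5 min after pacemaker entry)
  # beats the autonomous cap (300/60 + 18 = 23)
  expect_equal(tr$exit_maps[6, 41, 2], t_pm + 10 + 300 / 40)
})

test_that("invalid generator inputs are rejected", {
  g <- well_geometry(30, 30, 10, shape = "disk")
  expect_error(
    compute_entry_exit_maps(
      oscillator_field(40, 30, list(pacemaker(5, 5, 5))), g, 1),
    "outside the well mask")
  expect_error(oscillator_field(40, 30, list(pacemaker(150, 150, 45))),
               "advance must be smaller")
  expect_error(oscillator_field(v_exit_um_per_min = 80, v_entry_um_per_min = 60),
               "must not exceed")
  # non-convex mask
  m <- matrix(TRUE, 30, 30); m[10:20, 14:16] <- FALSE
  gnc <- well_geometry(30, 30, 10, mask = m)
  expect_error(compute_entry_exit_maps(oscillator_field(40, 30), gnc, 1),
               "convex")
})
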