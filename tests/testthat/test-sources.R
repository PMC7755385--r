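make_entry_map <- function(times, pixel_size_um = 13, frame_interval_min = 2,
                           cycle = 2L) {
  structure(list(times = times, cycle = cycle, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min),
            class = "entry_time_map")
}

test_that("each pacemaker yields exactly one source at its position", {
  sim <- sim_pipeline_well(advances = c(10, 8), noise_frac = 0)
  em <- make_entry_map(sim$truth$entry_maps[, , 2], 13, 2)
  reg <- detect_mitotic_regions(em)
  expect_length(reg$regions, 2)
  src <- extract_sources(reg)
  expect_equal(nrow(src), 2)
  pmtab <- sim$truth$pacemaker_table
  tol <- max(2 * 13, sim$field$v_entry_um_per_min * 2)
  for (i in seq_len(2)) {
    d <- min(sqrt((src$x_um - pmtab$x_um[i])^2 + (src$y_um - pmtab$y_um[i])^2))
    expect_lte(d, tol)
  }
})

test_that("concerted entry yields no localized sources", {
  tm <- matrix(30, 60, 60)
  tm[20:30, 20:30] <- NA  # a static, never-entering artifact
  reg <- detect_mitotic_regions(make_entry_map(tm))
  expect_true(reg$concerted)
  expect_length(reg$regions, 0)
  expect_equal(nrow(extract_sources(reg)), 0)
})

test_that("an empty entry map produces an empty region list", {
  reg <- detect_mitotic_regions(make_entry_map(matrix(NA_real_, 20, 20)))
  expect_length(reg$regions, 0)
  expect_false(reg$concerted)
})

test_that("dumbbell regions are split into two sources at the lobe centres", {
  s <- 6.5; h <- 80; w <- 80
  cx <- matrix(rep((1:w - 0.5) * s, each = h), h, w)
  cy <- matrix(rep((1:h - 0.5) * s, w), h, w)
  c1 <- c(160, 260); c2 <- c(360, 260)
  lobes <- pmin(sqrt((cx - c1[1])^2 + (cy - c1[2])^2),
                sqrt((cx - c2[1])^2 + (cy - c2[2])^2))
  dumb <- lobes <= 60 | (abs(cy - 260) <= 10 & cx >= 160 & cx <= 360)
  tm <- matrix(NA_real_, h, w)
  tm[dumb] <- 0
  d2 <- matrix(Inf, h, w)
  for (k in which(dumb)) d2 <- pmin(d2, (cx - cx[k])^2 + (cy - cy[k])^2)
  tm[!dumb] <- sqrt(d2[!dumb]) / 60
  reg <- detect_mitotic_regions(make_entry_map(tm, s, 2))
  src <- extract_sources(reg)
  expect_equal(nrow(src), 2)
  expect_true(all(src$split))
  expect_equal(src$onset_min, c(0, 0))
  d_match <- vapply(list(c1, c2), function(cc)
    min(sqrt((src$x_um - cc[1])^2 + (src$y_um - cc[2])^2)), 1)
  expect_true(all(d_match <= s))  # within one pixel of each disk centre
})

test_that("two well-separated regions keep independent onsets", {
  sim <- sim_pipeline_well(advances = c(12, 6), noise_frac = 0)
  em <- make_entry_map(sim$truth$entry_maps[, , 2], 13, 2)
  src <- extract_sources(detect_mitotic_regions(em))
  expect_equal(nrow(src), 2)
  expect_equal(sort(src$onset_min),
               sort(vapply(sim$truth$pacemaker_table$firing_times_min,
                           `[`, 1, 2)),
               tolerance = 1e-6)
})

test_that("classification follows the nucleus > centrosome > edge > other precedence", {
  g <- well_geometry(100, 100, 13)  # 1.3 mm square
  src <- tibble::tibble(region_id = 1:3, cycle = 2L,
                        x_um = c(650, 650, 650), y_um = c(650, 60, 650),
                        onset_min = c(30, 30, 30), split = FALSE)
  nuclei <- tibble::tibble(cycle = 2L, x_um = 700, y_um = 650,
                           t_first_min = 20, t_last_min = 28, intensity = 1)
  centrosomes <- cbind(620, 650)
  cls <- classify_sources(src, nuclei, centrosomes, g)
  # 50 um from a nucleus and 30 um from a centrosome: nucleus wins
  expect_equal(cls$class[1], "nucleus")
  expect_equal(cls$d_nucleus_um[1], 50)
  expect_equal(cls$d_centrosome_um[1], 30)
  # far from structures, 60 um from the boundary: edge
  cls2 <- classify_sources(src[2, ], NULL, NULL, g)
  expect_equal(cls2$class, "edge")
  # far from everything: other
  cls3 <- classify_sources(src[3, ], NULL, NULL, g)
  expect_equal(cls3$class, "other")
  # degenerate radius: nothing can be nuclear
  cls0 <- classify_sources(src, nuclei, NULL, g,
                           classification_params(proximity_radius_um = 0))
  expect_false(any(cls0$class == "nucleus"))
})

test_that("classification is deterministic and order-invariant", {
  g <- well_geometry(100, 100, 13)
  set.seed(5)
  src <- tibble::tibble(region_id = 1:8, cycle = 2L,
                        x_um = runif(8, 100, 1200), y_um = runif(8, 100, 1200),
                        onset_min = 30, split = FALSE)
  nuclei <- tibble::tibble(cycle = 2L, x_um = runif(3, 100, 1200),
                           y_um = runif(3, 100, 1200),
                           t_first_min = 20, t_last_min = 28, intensity = 1)
  a <- classify_sources(src, nuclei, NULL, g)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  b <- classify_sources(src[perm, ], nuclei[c(3, 1, 2), ], NULL, g)
  expect_equal(b$class, a$class[perm])
  expect_equal(b$d_nucleus_um, a$d_nucleus_um[perm])
})

test_that("benchmark region is the latest fraction with ties included", {
  tm_u <- matrix(25, 40, 40)
  bm_u <- benchmark_region(make_entry_map(tm_u), 0.15)
  expect_true(all(bm_u))   # single tie class covers everything

  tm_r <- matrix(rep(seq(0, 39), each = 40), 40, 40)  # linear ramp
  bm_r <- benchmark_region(make_entry_map(tm_r), 0.15)
  frac <- sum(bm_r) / length(tm_r)
  expect_lt(abs(frac - 0.15), 0.031)
  # the band is the trailing columns
  expect_true(all(which(colSums(bm_r) > 0) > 33))

  expect_error(benchmark_region(make_entry_map(matrix(NA_real_, 10, 10))),
               "no defined entries")
})

test_that("a strong pacemaker is excluded from the benchmark region", {
  sim <- sim_pipeline_well(advances = 12, noise_frac = 0)
  em <- make_entry_map(sim$truth$entry_maps[, , 2], 13, 2)
  bm <- benchmark_region(em, 0.15)
  pm <- sim$truth$pacemaker_table
  px <- wavepace:::um_to_pixel(sim$geometry, pm$x_um[1], pm$y_um[1])
  # no benchmark pixel within the entrained disk
  co <- wavepace:::pixel_coords_um(sim$geometry)
  r_entr <- sim$field$v_entry_um_per_min * pm$advance_min[1]
  inside <- sqrt((co$x - pm$x_um[1])^2 + (co$y - pm$y_um[1])^2) < r_entr
  expect_false(any(bm & inside))
})
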