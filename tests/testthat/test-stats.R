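test_that("bootstrap p-values agree with the exact binomial tail", {
  g <- well_geometry(60, 60, 10, shape = "disk")
  s <- g$pixel_size_um
  idx <- which(g$mask, arr.ind = TRUE)
  px <- cbind((idx[, "col"] - 0.5) * s, (idx[, "row"] - 0.5) * s)
  refs <- rbind(c(200, 200), c(420, 350))
  radius <- 100
  d2 <- pmin((px[, 1] - refs[1, 1])^2 + (px[, 2] - refs[1, 2])^2,
             (px[, 1] - refs[2, 1])^2 + (px[, 2] - refs[2, 2])^2)
  f_cov <- mean(d2 < radius^2)

  n_iter <- 2e4
  for (case in list(list(n = 8, k = 2), list(n = 15, k = 4), list(n = 15, k = 0))) {
    set.seed(10 + case$n + case$k)
    src <- tibble::tibble(x_um = px[sample(nrow(px), case$n), 1],
                          y_um = px[sample(nrow(px), case$n), 2])
    # plant exactly k proximal sources
    near <- pmin((src$x_um - refs[1, 1])^2 + (src$y_um - refs[1, 2])^2,
                 (src$x_um - refs[2, 1])^2 + (src$y_um - refs[2, 2])^2) < radius^2
    while (sum(near) != case$k) {
      i <- if (sum(near) > case$k) which(near)[1] else which(!near)[1]
      pool <- if (sum(near) > case$k) which(d2 >= radius^2) else which(d2 < radius^2)
      j <- sample(pool, 1)
      src$x_um[i] <- px[j, 1]; src$y_um[i] <- px[j, 2]
      near[i] <- !near[i]
    }
    bt <- bootstrap_proximity_pvalue(src, refs, g, radius, n_iter = n_iter, seed = 77)
    expect_equal(bt$observed_count, case$k)
    p_exact <- 1 - pbinom(case$k - 1, case$n, f_cov)
    se <- sqrt(p_exact * (1 - p_exact) / n_iter)
    expect_lt(abs(bt$p_value - p_exact), 3 * se + 1e-12)
  }
})

test_that("bootstrap degenerate cases and determinism", {
  g <- well_geometry(40, 40, 10, shape = "disk")
  src <- tibble::tibble(x_um = c(150, 250), y_um = c(200, 180))
  # a reference whose disk covers the whole well: saturation, p = 1
  bt_sat <- bootstrap_proximity_pvalue(src, cbind(200, 200), g,
                                       radius_um = 1000, n_iter = 2000, seed = 1)
  expect_equal(bt_sat$p_value, 1)
  # no reference points
  bt_none <- bootstrap_proximity_pvalue(src, NULL, g, n_iter = 10, seed = 1)
  expect_equal(bt_none$observed_count, 0L)
  expect_equal(bt_none$p_value, 1)
  # seeded reproducibility
  b1 <- bootstrap_proximity_pvalue(src, cbind(160, 210), g, 100, 5000, seed = 9)
  b2 <- bootstrap_proximity_pvalue(src, cbind(160, 210), g, 100, 5000, seed = 9)
  expect_identical(b1$p_value, b2$p_value)
  expect_identical(b1$null_counts, b2$null_counts)
})

test_that("mock nearest distances follow the analytic disk geometry", {
  g <- well_geometry(160, 160, 10, shape = "disk")  # radius 800 um
  src <- tibble::tibble(x_um = c(800, 700), y_um = c(800, 860))
  dd <- distance_distribution(src, cbind(800, 800), g, n_mock = 2000, seed = 3)
  for (r in c(200, 400, 600))
    expect_lt(abs(mean(dd$mock <= r) - (r / 800)^2), 0.02)

  # sources placed on the reference: observed distances are 0
  on_ref <- distance_distribution(tibble::tibble(x_um = c(795, 795),
                                                 y_um = c(795, 795)),
                                  cbind(795, 795), g, n_mock = 5, seed = 1)
  expect_true(all(on_ref$observed == 0))
})

test_that("planted proximity enrichment shows in the observed CDF", {
  g <- well_geometry(120, 120, 10, shape = "disk")
  refs <- cbind(c(400, 800), c(500, 700))
  set.seed(8)
  th <- runif(10, 0, 2 * pi)
  near <- cbind(refs[rep(1:2, 5), 1] + 60 * cos(th),
                refs[rep(1:2, 5), 2] + 60 * sin(th))
  idx <- which(g$mask, arr.ind = TRUE)
  far <- idx[sample(nrow(idx), 10), ]
  src <- tibble::tibble(x_um = c(near[, 1], (far[, "col"] - 0.5) * 10),
                        y_um = c(near[, 2], (far[, "row"] - 0.5) * 10))
  dd <- distance_distribution(src, refs, g, n_mock = 500, seed = 2)
  expect_gt(mean(dd$observed <= 100), mean(dd$mock <= 100))
})

test_that("class fractions aggregate correctly across experiments", {
  one <- tibble::tibble(experiment = "a", cycle = rep(1:3, each = 4),
                        class = "nucleus")
  c1 <- class_fraction_curves(one)
  expect_true(all(c1$mean_fraction[c1$class == "nucleus"] == 1))
  expect_true(all(c1$sem == 0))
  expect_false(any(c1$sem_defined))

  two <- tibble::tibble(
    experiment = rep(c("a", "b"), each = 10),
    cycle = 3L,
    class = c(rep("nucleus", 2), rep("other", 8),   # 0.2
              rep("nucleus", 4), rep("other", 6)))  # 0.4
  c2 <- class_fraction_curves(two)
  nuc <- c2[c2$class == "nucleus", ]
  expect_equal(nuc$mean_fraction, 0.3)
  expect_equal(nuc$sem, 0.1)
  # fractions sum to one within each cycle
  expect_equal(sum(c2$mean_fraction), 1, tolerance = 1e-9)
})

test_that("nuclear fraction rises when nuclear pacemakers appear", {
  set.seed(14)
  curves <- replicate(20, {
    rows <- list()
    for (cy in 1:5) {
      n_nuc <- if (cy >= 3) rpois(1, 2 + 2 * (cy - 2)) else 0
      n_oth <- rpois(1, 5) + 1
      rows[[cy]] <- tibble::tibble(
        experiment = "sim", cycle = cy,
        class = c(rep("nucleus", n_nuc), rep("other", n_oth)))
    }
    cc <- class_fraction_curves(do.call(rbind, rows))
    cc$mean_fraction[cc$class == "nucleus"]
  })
  mean_curve <- rowMeans(curves)
  expect_true(all(diff(mean_curve[2:5]) > 0))
  expect_equal(mean_curve[1], 0)
})

test_that("best sources are the earliest fraction with ties", {
  src <- tibble::tibble(onset_min = c(30, 31, 32, 33, 34, 35, 36, 37, 38, 39))
  expect_equal(best_sources(src, 0.10)$onset_min, 30)
  ties <- tibble::tibble(onset_min = rep(40, 6))
  expect_equal(nrow(best_sources(ties, 0.10)), 6)
})
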