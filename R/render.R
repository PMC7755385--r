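#' Rendering configuration for synthetic movies
#'
#' @param frame_interval_min Acquisition interval (min/frame); typical
#'   experiments use 0.5-2 min.
#' @param duration_min Movie length (min).
#' @param I_interphase,I_mitotic Tubulin-channel intensity plateaus
#'   (interphase microtubule arrays are bright, mitotic cytoplasm dim).
#' @param transition_width_min Width of the logistic ramp applied at entry
#'   and exit transitions (min; 0 gives a hard step).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param nls_amplitude Peak added intensity of a nuclear-reporter blob.
#' @param nls_blob_sigma_um Gaussian radius of a rendered nucleus.
#' @param nls_visible_fraction Fraction of each interphase, counted back from
#'   mitotic entry, during which nuclei are visible (0.5 = nuclei appear
#'   midway through interphase and disperse at entry).
#' @param seed RNG seed for the noise stream.
#' @return A `render_config` object.
#' @export
render_config <- function(frame_interval_min = 2, duration_min = NULL,
                          I_interphase = 200, I_mitotic = 80,
                          transition_width_min = 1, noise_sd = 0,
                          nls_amplitude = 150, nls_blob_sigma_um = 20,
                          nls_visible_fraction = 0.5, seed = 1L) {
  stopifnot(frame_interval_min > 0, I_interphase > I_mitotic, I_mitotic >= 0,
            transition_width_min >= 0, noise_sd >= 0,
            nls_visible_fraction > 0, nls_visible_fraction <= 1)
  structure(list(frame_interval_min = frame_interval_min,
                 duration_min = duration_min,
                 I_interphase = I_interphase, I_mitotic = I_mitotic,
                 transition_width_min = transition_width_min,
                 noise_sd = noise_sd, nls_amplitude = nls_amplitude,
                 nls_blob_sigma_um = nls_blob_sigma_um,
                 nls_visible_fraction = nls_visible_fraction,
                 seed = as.integer(seed)),
            class = "render_config")
}

# evaluate code with a locally seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

logistic_ramp <- function(t, width) {
  if (width <= 0) as.numeric(t >= 0) else 1 / (1 + exp(-t / width))
}

#' Render a two-channel movie from ground-truth entry/exit maps
#'
#' The tubulin channel sits at `I_interphase` outside mitosis and at
#' `I_mitotic` between each pixel's entry and exit time, with logistic ramps
#' of the configured width at both transitions. The NLS channel contains a
#' Gaussian blob per nucleus in `truth$nucleus_truth`, visible during the
#' trailing `nls_visible_fraction` of the local interphase and extinguished
#' at local mitotic entry (nuclear envelope breakdown). Additive Gaussian
#' noise is applied to both channels inside the mask; pixels outside the
#' mask are zero.
#'
#' @param truth A `ground_truth` from [compute_entry_exit_maps()].
#' @param field The generating [oscillator_field()].
#' @param geometry The [well_geometry()].
#' @param render A [render_config()]; `duration_min` defaults to the last
#'   exit time plus three ramp widths.
#' @return A [movie()] with channels `tubulin` and `nls`.
#' @export
render_movie <- function(truth, field, geometry, render = render_config()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(render, "render_config"))
  if (render$frame_interval_min <= 0) stop("frame interval must be positive")
  h <- geometry$height_px; w <- geometry$width_px
  mask <- geometry$mask
  dur <- render$duration_min
  if (is.null(dur))
    dur <- max(truth$exit_maps, na.rm = TRUE) + 3 * max(render$transition_width_min, 1)
  times <- seq(0, dur, by = render$frame_interval_min)
  nt <- length(times)
  wd <- render$transition_width_min
  dI <- render$I_mitotic - render$I_interphase

  # overlapping consecutive cycles would make the rendered trace ambiguous
  if (truth$n_cycles > 1) {
    for (c_i in seq_len(truth$n_cycles - 1)) {
      ov <- truth$exit_maps[, , c_i] >= truth$entry_maps[, , c_i + 1]
      if (any(ov, na.rm = TRUE))
        warning("mitosis of cycle ", c_i, " overlaps entry of cycle ", c_i + 1,
                " at ", sum(ov, na.rm = TRUE), " pixels")
    }
  }

  tub <- array(0, c(h, w, nt))
  base <- matrix(render$I_interphase, h, w)
  for (f in seq_len(nt)) {
    fr <- base
    for (c_i in seq_len(truth$n_cycles)) {
      Tc <- truth$entry_maps[, , c_i]; Ec <- truth$exit_maps[, , c_i]
      fr <- fr + dI * (logistic_ramp(times[f] - Tc, wd) -
                         logistic_ramp(times[f] - Ec, wd))
    }
    fr[!mask] <- 0
    tub[, , f] <- fr
  }

  nls <- array(0, c(h, w, nt))
  if (nrow(truth$nucleus_truth) > 0) {
    co <- pixel_coords_um(geometry)
    sig <- render$nls_blob_sigma_um
    for (i in seq_len(nrow(truth$nucleus_truth))) {
      nu <- truth$nucleus_truth[i, ]
      px <- um_to_pixel(geometry, nu$x_um, nu$y_um)
      c_i <- nu$cycle
      t_entry <- truth$entry_maps[px[1, "row"], px[1, "col"], c_i]
      t_start_iphase <- if (c_i == 1) 0 else truth$exit_maps[px[1, "row"], px[1, "col"], c_i - 1]
      if (is.na(t_entry) || is.na(t_start_iphase)) next
      t_on <- t_entry - render$nls_visible_fraction * (t_entry - t_start_iphase)
      vis <- which(times >= t_on & times < t_entry)
      if (!length(vis)) next
      rr <- max(1, px[1, "row"] - ceiling(3 * sig / geometry$pixel_size_um)):
        min(h, px[1, "row"] + ceiling(3 * sig / geometry$pixel_size_um))
      cc <- max(1, px[1, "col"] - ceiling(3 * sig / geometry$pixel_size_um)):
        min(w, px[1, "col"] + ceiling(3 * sig / geometry$pixel_size_um))
      blob <- render$nls_amplitude *
        exp(-((co$x[rr, cc, drop = FALSE] - nu$x_um)^2 +
                (co$y[rr, cc, drop = FALSE] - nu$y_um)^2) / (2 * sig^2))
      blob[!mask[rr, cc, drop = FALSE]] <- 0
      for (f in vis) nls[rr, cc, f] <- nls[rr, cc, f] + blob
    }
  }

  if (render$noise_sd > 0) {
    with_local_seed(render$seed, {
      nmask <- as.vector(mask)
      for (f in seq_len(nt)) {
        e1 <- matrix(rnorm(h * w, sd = render$noise_sd), h, w)
        e2 <- matrix(rnorm(h * w, sd = render$noise_sd), h, w)
        e1[!mask] <- 0; e2[!mask] <- 0
        tub[, , f] <- tub[, , f] + e1
        nls[, , f] <- nls[, , f] + e2
      }
    })
  }

  movie(list(tubulin = tub, nls = nls),
        pixel_size_um = geometry$pixel_size_um,
        frame_interval_min = render$frame_interval_min)
}

#' Simulate a nucleus lineage across cycles
#'
#' Each nucleus independently either persists or divides into two daughters
#' displaced symmetrically by `displacement_um` in a random direction at each
#' cycle, emulating the roughly exponential (but sub-doubling) growth of
#' nucleus counts in sperm-supplemented extracts. Daughters falling outside
#' the mask are clamped to the nearest valid pixel.
#'
#' @param initial_positions Two-column matrix or data frame of (x_um, y_um)
#'   positions present at `first_cycle`.
#' @param division_prob_per_cycle Probability a nucleus divides at each
#'   mitosis (expected per-cycle fold change is `1 + p`).
#' @param displacement_um Half-separation of daughter nuclei.
#' @param n_cycles Number of cycles to populate.
#' @param geometry A [well_geometry()].
#' @param seed RNG seed.
#' @param first_cycle Cycle index of the initial positions (default 1).
#' @return Tibble (cycle, id, x_um, y_um); the `clamped` attribute counts
#'   daughters pulled back inside the mask.
#' @export
simulate_nucleus_lineage <- function(initial_positions, division_prob_per_cycle,
                                     displacement_um, n_cycles, geometry,
                                     seed = 1L, first_cycle = 1L) {
  stopifnot(division_prob_per_cycle >= 0, division_prob_per_cycle <= 1,
            n_cycles >= 1)
  pos <- as.matrix(as.data.frame(initial_positions))[, 1:2, drop = FALSE]
  colnames(pos) <- c("x_um", "y_um")
  valid_idx <- which(geometry$mask, arr.ind = TRUE)
  s <- geometry$pixel_size_um
  clamp <- function(p) {
    px <- um_to_pixel(geometry, p[1], p[2])
    if (geometry$mask[px[1, "row"], px[1, "col"]]) return(c(p, 0))
    d2 <- (valid_idx[, "row"] - px[1, "row"])^2 + (valid_idx[, "col"] - px[1, "col"])^2
    k <- which.min(d2)
    c((valid_idx[k, "col"] - 0.5) * s, (valid_idx[k, "row"] - 0.5) * s, 1)
  }
  out <- list()
  n_clamped <- 0L
  with_local_seed(seed, {
    for (c_i in seq(first_cycle, first_cycle + n_cycles - 1L)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        cycle = as.integer(c_i), id = seq_len(nrow(pos)),
        x_um = pos[, 1], y_um = pos[, 2])
      if (c_i == first_cycle + n_cycles - 1L) break
      nxt <- list()
      for (i in seq_len(nrow(pos))) {
        if (runif(1) < division_prob_per_cycle) {
          th <- runif(1, 0, 2 * pi)
          d <- c(cos(th), sin(th)) * displacement_um
          a <- clamp(pos[i, ] + d); b <- clamp(pos[i, ] - d)
          n_clamped <- n_clamped + a[3] + b[3]
          nxt[[length(nxt) + 1L]] <- rbind(a[1:2], b[1:2])
        } else {
          nxt[[length(nxt) + 1L]] <- pos[i, , drop = FALSE]
        }
      }
      pos <- do.call(rbind, nxt)
    }
  })
  res <- do.call(rbind, out)
  attr(res, "clamped") <- n_clamped
  res
}
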