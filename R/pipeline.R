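#' Simulate a complete well
#'
#' Convenience wrapper around the kinematic generator: builds the geometry,
#' oscillator field and ground truth, renders the two-channel movie, and
#' (for nucleus-kind pacemakers) plants co-located NLS nuclei in every cycle
#' from the second onward, when reconstituted nuclei typically become
#' visible.
#'
#' @param side_mm Well side length (square well).
#' @param pixel_size_um Pixel size (um/px).
#' @param pacemakers Data frame with columns `x_um`, `y_um`, `advance_min`,
#'   and optionally `radius_um`, `kind`.
#' @param n_cycles Cycles to simulate.
#' @param base_period_min,phase0_min,v_entry,v_exit,mitosis_min,mitosis_bulk_min
#'   Oscillator-field parameters, see [oscillator_field()].
#' @param frame_interval_min Acquisition interval.
#' @param noise_frac Additive noise SD as a fraction of the tubulin dynamic
#'   range.
#' @param duration_min Movie length (default: covers all simulated cycles).
#' @param seed RNG seed for rendering noise.
#' @return List with `geometry`, `field`, `truth`, `movie`.
#' @export
simulate_well <- function(side_mm = 3.2, pixel_size_um = 13,
                          pacemakers = NULL, n_cycles = 2,
                          base_period_min = 40, phase0_min = 10,
                          v_entry = 60, v_exit = 40,
                          mitosis_min = 10, mitosis_bulk_min = 18,
                          frame_interval_min = 2, noise_frac = 0.1,
                          duration_min = NULL, seed = 1L) {
  npx <- round(side_mm * 1000 / pixel_size_um)
  geometry <- well_geometry(npx, npx, pixel_size_um)
  if (!is.null(pacemakers)) pacemakers <- as.data.frame(pacemakers)
  pms <- list()
  if (!is.null(pacemakers) && nrow(pacemakers) > 0) {
    for (i in seq_len(nrow(pacemakers))) {
      pms[[i]] <- pacemaker(
        pacemakers$x_um[i], pacemakers$y_um[i], pacemakers$advance_min[i],
        radius_um = if ("radius_um" %in% names(pacemakers)) pacemakers$radius_um[i] else 30,
        kind = if ("kind" %in% names(pacemakers)) pacemakers$kind[i] else "other")
    }
  }
  field <- oscillator_field(base_period_min, phase0_min, pms, v_entry, v_exit,
                            mitosis_min, mitosis_bulk_min)
  truth <- compute_entry_exit_maps(field, geometry, n_cycles)

  nuc_pm <- which(vapply(pms, function(p) p$kind == "nucleus", TRUE))
  if (length(nuc_pm) && n_cycles >= 2) {
    rows <- list()
    for (c_i in 2:n_cycles) {
      for (k in nuc_pm) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          cycle = as.integer(c_i), id = k,
          x_um = pms[[k]]$x_um, y_um = pms[[k]]$y_um)
      }
    }
    truth$nucleus_truth <- do.call(rbind, rows)
  }

  rc <- render_config(frame_interval_min = frame_interval_min,
                      duration_min = duration_min,
                      noise_sd = noise_frac * (200 - 80), seed = seed)
  list(geometry = geometry, field = field, truth = truth,
       movie = render_movie(truth, field, geometry, rc))
}

#' Analyse one cycle of a movie end to end
#'
#' Runs the full analysis chain: well mask, per-pixel cycle decomposition,
#' mitotic-region detection in the focal cycle, source extraction and
#' classification, the slowest-fraction benchmark, and per-source
#' delta-cycle times.
#'
#' @param movie A [movie()].
#' @param cycle Focal cycle (needs a preceding cycle for durations).
#' @param geometry Optional [well_geometry()] (else from [make_well_mask()]).
#' @param centrosomes Optional (x_um, y_um) point list.
#' @param seg_params,src_params,cls_params Module parameter objects.
#' @param benchmark_fraction Slowest fraction of the well used as reference.
#' @param detect_nuclei_blobs Detect nuclei from the NLS channel (default:
#'   only if the channel carries signal).
#' @return List: `geometry`, `series`, `regions`, `sources` (classified,
#'   with delta-cycle columns), `benchmark`, `nuclei`.
#' @export
analyze_well <- function(movie, cycle = 2, geometry = NULL,
                         centrosomes = NULL,
                         seg_params = segmentation_params(),
                         src_params = source_params(),
                         cls_params = classification_params(),
                         benchmark_fraction = 0.15,
                         detect_nuclei_blobs = NULL) {
  if (is.null(geometry)) geometry <- make_well_mask(movie)
  series <- segment_movie(movie, geometry, params = seg_params)
  if (series$n_cycles < cycle)
    stop(sprintf("only %d cycle(s) segmented; cycle %d requested",
                 series$n_cycles, cycle))
  cur <- entry_time_map(series, cycle)
  prev <- if (cycle > 1) entry_time_map(series, cycle - 1) else NULL

  regions <- detect_mitotic_regions(cur, params = src_params)
  sources <- extract_sources(regions, src_params)

  if (is.null(detect_nuclei_blobs))
    detect_nuclei_blobs <- "nls" %in% names(movie$channels) &&
      max(movie$channels$nls) > 6 * sd(movie$channels$nls[, , 1])
  nuclei <- if (detect_nuclei_blobs)
    detect_nuclei(movie, series) else NULL

  if (nrow(sources) > 0) {
    sources <- classify_sources(sources, nuclei, centrosomes, geometry, cls_params)
    bench <- benchmark_region(cur, benchmark_fraction)
    if (!is.null(prev))
      sources <- delta_cycle_times(sources, prev, cur, bench)
  } else bench <- benchmark_region(cur, benchmark_fraction)

  list(geometry = geometry, series = series, regions = regions,
       sources = sources, benchmark = bench, nuclei = nuclei)
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis chain; unknown keys are
#' rejected so that a run manifest always reflects the full configuration.
#'
#' @param input Sidecar YAML path of an input movie (see [read_movie()]),
#'   or `NULL` when `simulate` is given.
#' @param simulate Named list of [simulate_well()] arguments, or `NULL`.
#' @param cycle Focal cycle to analyse.
#' @param theta_entry Entry-crossing level.
#' @param proximity_radius_um,edge_band_um Classification radii.
#' @param benchmark_fraction Slowest fraction used as reference.
#' @param best_fraction Earliest fraction reported as "best" sources.
#' @param n_iter Bootstrap iterations.
#' @param seed Global seed.
#' @param experiment_id Label written into the sources table.
#' @param out_dir Output directory.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, cycle = 2,
                            theta_entry = 0.75, proximity_radius_um = 100,
                            edge_band_um = 100, benchmark_fraction = 0.15,
                            best_fraction = 0.10, n_iter = 1e5, seed = 1L,
                            experiment_id = "run", out_dir = "wavepace_run") {
  cfg <- list(input = input, simulate = simulate, cycle = cycle,
              theta_entry = theta_entry,
              proximity_radius_um = proximity_radius_um,
              edge_band_um = edge_band_um,
              benchmark_fraction = benchmark_fraction,
              best_fraction = best_fraction, n_iter = n_iter,
              seed = as.integer(seed), experiment_id = experiment_id,
              out_dir = out_dir)
  structure(cfg, class = "pipeline_config")
}

#' Validate a raw configuration list against [pipeline_config()]
#' @param x Named list.
#' @return A `pipeline_config`.
#' @export
as_pipeline_config <- function(x) {
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, x)
}

#' Run the full pipeline into an output directory
#'
#' Simulates or loads a movie, analyses the focal cycle, and writes the
#' sources CSV (with delta-cycle times), the benchmark heat map, the
#' bootstrap JSON (when nuclei are present), a log, and a manifest carrying
#' the configuration, its hash and the package version. Deterministic for a
#' fixed configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                                       sprintf(...)), file = logf, append = TRUE)
  cat("", file = logf)
  stage <- "setup"
  res <- tryCatch({
    stage <- "input"
    sim <- NULL
    mv <- if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- config$seed
      sim <- do.call(simulate_well, sim_args)
      logline("simulated well: %d pacemakers",
              nrow(sim$truth$pacemaker_table))
      sim$movie
    } else {
      if (is.null(config$input)) stop("config needs either input or simulate")
      read_movie(config$input)
    }

    stage <- "analysis"
    ana <- analyze_well(mv, cycle = config$cycle,
                        seg_params = segmentation_params(theta_entry = config$theta_entry),
                        cls_params = classification_params(config$proximity_radius_um,
                                                           config$edge_band_um),
                        benchmark_fraction = config$benchmark_fraction)
    logline("cycle %d: %d sources (%s)", config$cycle, nrow(ana$sources),
            if (ana$regions$concerted) "concerted" else "wave-borne")

    stage <- "outputs"
    src <- ana$sources
    if (nrow(src) > 0) {
      src$experiment_id <- config$experiment_id
      write_sources_csv(src, file.path(config$out_dir, "sources.csv"))
      bs <- best_sources(src, config$best_fraction)
      write_sources_csv(bs, file.path(config$out_dir, "best_sources.csv"))
    }
    cur <- entry_time_map(ana$series, config$cycle)
    hm <- entry_heatmap(cur, ana$benchmark)
    grDevices::png(file.path(config$out_dir, "heatmap.png"), width = 600, height = 600)
    plot(hm)
    grDevices::dev.off()
    rel <- hm$rel_times; rel[is.na(rel)] <- 0
    tiff::writeTIFF(rel / max(rel, 1), file.path(config$out_dir, "heatmap.tif"),
                    bits.per.sample = 32L)

    if (!is.null(ana$nuclei) && nrow(ana$nuclei) > 0 && nrow(src) > 0) {
      stage <- "bootstrap"
      nuc <- ana$nuclei[!is.na(ana$nuclei$cycle) & ana$nuclei$cycle == config$cycle, ]
      if (nrow(nuc) > 0) {
        bt <- bootstrap_proximity_pvalue(src, nuc[, c("x_um", "y_um")],
                                         ana$geometry,
                                         radius_um = config$proximity_radius_um,
                                         n_iter = config$n_iter,
                                         seed = config$seed)
        jsonlite::write_json(list(observed_count = bt$observed_count,
                                  n_sources = bt$n_sources, n_iter = bt$n_iter,
                                  null_mean = bt$null_mean, p_value = bt$p_value,
                                  p_value_label = bt$p_value_label),
                             file.path(config$out_dir, "bootstrap.json"),
                             auto_unbox = TRUE, digits = NA)
        logline("bootstrap: p = %s", bt$p_value_label)
      }
    }

    cfg_plain <- unclass(config)
    manifest <- list(config = cfg_plain,
                     config_hash = sum(utf8ToInt(paste(deparse(cfg_plain), collapse = ""))),
                     package_version = as.character(utils::packageVersion("wavepace")))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
    logline("done")
    ana
  }, error = function(e) {
    logline("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(structure(config$out_dir, analysis = res))
}
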