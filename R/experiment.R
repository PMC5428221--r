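# Experiment orchestration: structured configuration, the end-to-end
# radiography experiment, and the frame-averaging study.

#' Default experiment configuration
#'
#' Mirrors the reference acquisition: 40 kVp tungsten spectrum with an
#' 8 keV low-energy cut-off, Nb/Mo and Pd/Ag filter pairs, a 512 x 512
#' two-foil phantom at 11 um pixels, and the weighted band-subtraction
#' pipeline with a 2% pedestal on the high-band pair.
#'
#' @param ... Named overrides merged (recursively) into the defaults, e.g.
#'   `source = list(seed = 7)`.
#' @return Nested list of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    source = list(kvp = 40, cutoff_keV = 8, bin_width_keV = 0.05,
                  flat_counts = 1e4, exposure_scale = 1, seed = NULL,
                  spectrum_csv = NULL),
    filters = list(
      minus = list(low = list(element = "Nb", thickness_um = 30),
                   high = list(element = "Mo", thickness_um = 24)),
      plus = list(low = list(element = "Pd", thickness_um = 25),
                  high = list(element = "Ag", thickness_um = 27))),
    phantom = list(kind = "foil_fixture", shape = c(512, 512), pixel_um = 11,
                   rh_um = 12, ni_um = 18, overlap_element = "Ni",
                   path = NULL),
    pipeline = list(mode = "band-intensity", subtraction = "weighted",
                    weight_exponent = 3, rebalance = TRUE,
                    pedestal_fraction = 0.02, pedestal_filters = "plus",
                    n_frames = 1, response = "counting"),
    rois = NULL)
  over <- list(...)
  merge <- function(base, x) {
    for (nm in names(x)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(x[[nm]])) {
        merge(base[[nm]], x[[nm]])
      } else {
        x[[nm]]
      }
    }
    base
  }
  structure(merge(cfg, over), class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' @param path YAML file; keys override [experiment_config()] defaults.
#' @return An `experiment_config`.
#' @export
load_config <- function(path) {
  do.call(experiment_config, yaml::read_yaml(path))
}

#' Validate an experiment configuration
#'
#' @param config An `experiment_config`.
#' @return The config, invisibly; errors name the offending field.
#' @export
validate_config <- function(config) {
  fail <- function(field, msg) {
    stop(sprintf("invalid config field '%s': %s", field, msg), call. = FALSE)
  }
  s <- config$source
  if (!is.numeric(s$kvp) || s$kvp <= 0) fail("source.kvp", "must be positive")
  if (s$cutoff_keV <= 0 || s$cutoff_keV >= s$kvp) {
    fail("source.cutoff_keV", "must lie in (0, kvp)")
  }
  if (!is.null(s$seed) && s$seed != as.integer(s$seed)) {
    fail("source.seed", "must be an integer")
  }
  for (b in c("minus", "plus")) {
    for (side in c("low", "high")) {
      f <- config$filters[[b]][[side]]
      known <- tryCatch({element_info(f$element); TRUE},
                        error = function(e) FALSE)
      if (!known) {
        fail(sprintf("filters.%s.%s.element", b, side),
             sprintf("unknown element '%s'", f$element))
      }
      if (!is.numeric(f$thickness_um) || f$thickness_um <= 0) {
        fail(sprintf("filters.%s.%s.thickness_um", b, side), "must be > 0")
      }
    }
  }
  ph <- config$phantom
  if (!ph$kind %in% c("foil_fixture", "path")) {
    fail("phantom.kind", "must be 'foil_fixture' or 'path'")
  }
  if (ph$kind == "foil_fixture") {
    for (el in ph$overlap_element) {
      known <- tryCatch({element_info(el); TRUE}, error = function(e) FALSE)
      if (!known) fail("phantom.overlap_element", sprintf("unknown element '%s'", el))
    }
  }
  p <- config$pipeline
  if (!p$mode %in% c("band-intensity", "log-difference")) {
    fail("pipeline.mode", "unknown subtraction mode")
  }
  if (!p$subtraction %in% c("weighted", "plain")) {
    fail("pipeline.subtraction", "must be 'weighted' or 'plain'")
  }
  if (p$pedestal_fraction < 0 || p$pedestal_fraction > 1) {
    fail("pipeline.pedestal_fraction", "must be in [0, 1]")
  }
  if (!is.numeric(p$n_frames) || p$n_frames < 1) {
    fail("pipeline.n_frames", "must be a positive integer")
  }
  invisible(config)
}

.config_spectrum <- function(config) {
  s <- config$source
  if (!is.null(s$spectrum_csv)) {
    load_spectrum(s$spectrum_csv, bin_width = s$bin_width_keV)
  } else {
    simulate_spectrum(tube_kVp = s$kvp, bin_width_keV = s$bin_width_keV,
                      low_cutoff_keV = s$cutoff_keV)
  }
}

.config_pairs <- function(config) {
  f <- config$filters
  list(minus = ross_pair(filter_spec(f$minus$low$element, f$minus$low$thickness_um),
                         filter_spec(f$minus$high$element, f$minus$high$thickness_um)),
       plus = ross_pair(filter_spec(f$plus$low$element, f$plus$low$thickness_um),
                        filter_spec(f$plus$high$element, f$plus$high$thickness_um)))
}

.config_phantom <- function(config) {
  ph <- config$phantom
  if (ph$kind == "path") {
    list(phantom = read_phantom(ph$path), rois = config$rois)
  } else {
    fx <- foil_fixture(shape = ph$shape, pixel_um = ph$pixel_um,
                       rh_um = ph$rh_um, ni_um = ph$ni_um,
                       overlap_element = ph$overlap_element)
    if (!is.null(config$rois)) fx$rois <- config$rois
    fx
  }
}

.map_metrics <- function(map, rois, n_frames) {
  list(snr = snr(map, rois$rh, rois$background),
       eps_res = eps_res(map, rois$residue, rois$rh),
       eps_over = eps_over(map, rois$rh, rois$overlap),
       n_frames = n_frames)
}

#' Run a complete imaging experiment from a configuration
#'
#' Builds the spectrum, phantom and filter pairs, runs
#' [ross_map_pipeline()], computes the quality metrics over the configured
#' ROIs, and (optionally) writes all artefacts - the four radiographs and
#' flats, both band absorbances, the final map, a metrics JSON, the
#' resolved configuration and a log - into `out_dir`.
#'
#' @param config An `experiment_config`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `map`, `metrics`, `pipeline` (the full
#'   [ross_map_pipeline()] result), `rois` and `config`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  validate_config(config)
  spectrum <- .config_spectrum(config)
  pairs <- .config_pairs(config)
  fx <- .config_phantom(config)
  p <- config$pipeline
  res <- ross_map_pipeline(fx$phantom, spectrum, pairs,
                           flat_counts = config$source$flat_counts,
                           exposure_scale = config$source$exposure_scale,
                           n_frames = p$n_frames,
                           noise_seed = config$source$seed,
                           pedestal_fraction = p$pedestal_fraction,
                           pedestal_filters = p$pedestal_filters,
                           mode = p$mode, subtraction = p$subtraction,
                           weight_exponent = p$weight_exponent,
                           rebalance = isTRUE(p$rebalance),
                           response = p$response)
  metrics <- .map_metrics(res$map, fx$rois, p$n_frames)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(res$radiographs)) {
      rg <- res$radiographs[[nm]]
      .write_scaled_tiff(rg$counts, file.path(out_dir, paste0(nm, ".tif")))
      .write_scaled_tiff(rg$flat, file.path(out_dir, paste0(nm, "_flat.tif")))
    }
    jsonlite::write_json(
      lapply(res$radiographs, function(rg) {
        list(filter = list(element = rg$filter$element,
                           thickness_um = rg$filter$thickness_um),
             exposure = rg$exposure, n_frames = rg$n_frames,
             seed = config$source$seed)
      }),
      file.path(out_dir, "radiographs.json"), auto_unbox = TRUE, digits = NA)
    .write_scaled_tiff(res$A_minus$A, file.path(out_dir, "band_minus.tif"))
    .write_scaled_tiff(res$A_plus$A, file.path(out_dir, "band_plus.tif"))
    .write_scaled_tiff(res$map$F, file.path(out_dir, "elemental_map.tif"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_plain <- rapply(unclass(config), identity, how = "replace")
    yaml::write_yaml(cfg_plain, file.path(out_dir, "config.yaml"))
    writeLines(c(sprintf("rossfilter %s",
                         as.character(utils::packageVersion("rossfilter"))),
                 sprintf("run at: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                 sprintf("seed: %s",
                         if (is.null(config$source$seed)) "none (noise-free)"
                         else config$source$seed),
                 sprintf("weight: %.6f", res$weight)),
               file.path(out_dir, "log.txt"))
  }
  list(map = res$map, metrics = metrics, pipeline = res, rois = fx$rois,
       config = config)
}

#' Frame-averaging study
#'
#' Repeats the pipeline while averaging increasing numbers of noisy frames
#' per filter and tabulates the quality metrics.  Frame sets are nested
#' (the N = 5 average reuses the first frame of N = 1, and so on), the way
#' an averaging study subsets one acquired series.
#'
#' @param config An `experiment_config` with a seed set (noise enabled).
#' @param frame_counts Numbers of frames to average.
#' @param csv Optional path for a CSV copy of the table.
#' @return `data.frame(n_frames, snr, eps_res, eps_over)`.
#' @export
averaging_study <- function(config = experiment_config(),
                            frame_counts = c(1, 5, 10, 20, 30, 50),
                            csv = NULL) {
  validate_config(config)
  if (any(frame_counts < 1)) stop("frame counts must be positive", call. = FALSE)
  if (is.null(config$source$seed)) {
    stop("averaging study needs noise: set source$seed", call. = FALSE)
  }
  spectrum <- .config_spectrum(config)
  pairs <- .config_pairs(config)
  fx <- .config_phantom(config)
  p <- config$pipeline
  n_max <- max(frame_counts)
  filters <- list(minus_low = pairs$minus$low, minus_high = pairs$minus$high,
                  plus_low = pairs$plus$low, plus_high = pairs$plus$high)
  # simulate the full nested series once per filter
  frames <- lapply(seq_along(filters), function(i) {
    lapply(seq_len(n_max), function(j) {
      simulate_radiograph(fx$phantom, spectrum, filters[[i]],
                          flat_counts = config$source$flat_counts,
                          exposure_scale = config$source$exposure_scale,
                          noise_seed = as.integer(config$source$seed) +
                            10000L * i + 100L * (j - 1L),
                          response = p$response)
    })
  })
  names(frames) <- names(filters)
  rows <- lapply(frame_counts, function(n) {
    rgs <- lapply(frames, function(fr) average_frames(fr[seq_len(n)]))
    ped <- function(rg) {
      rg$counts <- pedestal_threshold(rg$counts, p$pedestal_fraction)
      rg
    }
    if (p$pedestal_fraction > 0 && p$pedestal_filters %in% c("plus", "both")) {
      rgs$plus_low <- ped(rgs$plus_low); rgs$plus_high <- ped(rgs$plus_high)
    }
    if (p$pedestal_fraction > 0 && p$pedestal_filters %in% c("minus", "both")) {
      rgs$minus_low <- ped(rgs$minus_low); rgs$minus_high <- ped(rgs$minus_high)
    }
    c_minus <- if (isTRUE(p$rebalance)) {
      out_of_band_ratio(spectrum, pairs$minus, p$response)
    } else 1
    c_plus <- if (isTRUE(p$rebalance)) {
      out_of_band_ratio(spectrum, pairs$plus, p$response)
    } else 1
    A_minus <- band_absorbance(rgs$minus_high, rgs$minus_low, "minus", p$mode,
                               rebalance = c_minus)
    A_plus <- band_absorbance(rgs$plus_high, rgs$plus_low, "plus", p$mode,
                              rebalance = c_plus)
    w <- if (p$subtraction == "weighted") {
      map_weight(spectrum, pairs, p$weight_exponent)
    } else 1
    m <- .map_metrics(elemental_map(A_minus, A_plus, w), fx$rois, n)
    data.frame(n_frames = n, snr = m$snr, eps_res = m$eps_res,
               eps_over = m$eps_over)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  tab
}
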