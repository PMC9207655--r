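#' Run configuration for end-to-end studies
#'
#' Bundles every knob of the full analysis -- wavelength presets, SDS grid,
#' Monte Carlo settings, detection-model parameters and flow-phantom
#' settings -- into one validated object that can be saved to and loaded
#' from JSON.  Every output written by [reproduce_study()] records the
#' configuration hash and seed.
#'
#' @param wavelengths Preset names (subset of `"488"`, `"640"`, `"780"`).
#' @param sds_mm SDS grid, mm.
#' @param volume_extent_mm,voxel_size_mm Simulation domain.
#' @param n_photons Photons per Green's function.
#' @param time_gate_ns MC time gate.
#' @param seed Global seed.
#' @param noise_fraction,baseline_fraction,threshold_multiple Detection
#'   model parameters (see [detection_model()]).
#' @param calibration_anchor List with `wavelength`, `sds_mm`, `depth_mm`:
#'   the measured maximum detection depth used to pin the cell yield
#'   (default: 780 nm, 0.3-mm SDS, 3.5 mm).
#' @param phantom A [flow_phantom_config()]-style list of overrides for the
#'   synthetic traces.
#' @param out_dir Output directory for [reproduce_study()].
#'
#' @return An object of class `"difc_run_config"`.
#' @export
difc_run_config <- function(wavelengths = c("488", "640", "780"),
                            sds_mm = c(0.3, 1, 2, 3, 5, 6, 12),
                            volume_extent_mm = 50,
                            voxel_size_mm = 0.25,
                            n_photons = 1e8,
                            time_gate_ns = 5,
                            seed = 1L,
                            noise_fraction = 0.002,
                            baseline_fraction = 0.1,
                            threshold_multiple = 5,
                            calibration_anchor = list(wavelength = "780",
                                                      sds_mm = 0.3,
                                                      depth_mm = 3.5),
                            phantom = list(),
                            out_dir = "difc-out") {
  wavelengths <- as.character(wavelengths)
  valid <- c("488", "640", "780")
  bad <- setdiff(wavelengths, valid)
  if (length(bad)) {
    stop("unknown wavelength preset(s) ", paste(bad, collapse = ", "),
         "; available presets: ", paste(valid, collapse = ", "))
  }
  cfg <- structure(
    list(wavelengths = wavelengths, sds_mm = as.numeric(sds_mm),
         volume_extent_mm = volume_extent_mm,
         voxel_size_mm = voxel_size_mm,
         n_photons = n_photons, time_gate_ns = time_gate_ns,
         seed = as.integer(seed),
         noise_fraction = noise_fraction,
         baseline_fraction = baseline_fraction,
         threshold_multiple = threshold_multiple,
         calibration_anchor = calibration_anchor,
         phantom = phantom, out_dir = out_dir),
    class = "difc_run_config")
  # constructor-level validation via the component constructors
  voxel_volume(cfg$volume_extent_mm, cfg$voxel_size_mm)
  mc_config(cfg$n_photons, cfg$time_gate_ns, cfg$seed)
  detection_model(noise_fraction = cfg$noise_fraction,
                  baseline_fraction = cfg$baseline_fraction,
                  threshold_multiple = cfg$threshold_multiple)
  cfg
}

#' Save or load a run configuration as JSON
#'
#' Round-trip safe: every field of the configuration is preserved.
#'
#' @param config A [difc_run_config()].
#' @param path JSON file path.
#' @return `load_config()` returns the validated `"difc_run_config"`;
#'   `save_config()` returns `path` invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "difc_run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(difc_run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(difc_run_config, raw)
}

#' Stable hash of a run configuration
#'
#' MD5 of the canonical JSON serialization; stamped into every output file
#' for provenance.
#'
#' @param config A [difc_run_config()].
#' @return A hex string.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a fluence field or sensitivity map as a NIfTI volume + JSON sidecar
#'
#' Requires the `RNifti` package.  The sidecar records the optical
#' properties, source/detector geometry, photon budget and seed.
#'
#' @param x A `"fluence_field"` or `"sensitivity_map"`.
#' @param path Output path without extension; writes `<path>.nii.gz` and
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing volumes requires the 'RNifti' package")
  }
  values <- if (inherits(x, "sensitivity_map")) x$W else x$values
  img <- RNifti::asNifti(values, pixdim = rep(x$volume$voxel_size, 3))
  RNifti::writeNifti(img, paste0(path, ".nii.gz"))
  meta <- list(class = class(x)[1],
               voxel_size_mm = x$volume$voxel_size,
               extent_mm = x$volume$extent,
               props = x$props[c("mu_a", "mu_s", "g", "n", "wavelength_nm")])
  if (inherits(x, "sensitivity_map")) {
    meta$source_position <- x$source_position
    meta$detector_position <- x$detector_position
    meta$sds_mm <- x$sds
  } else {
    meta$source_position <- x$source_position
    meta$n_photons <- x$config$n_photons
    meta$seed <- x$config$seed
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a two-channel trace and its event log as CSV
#'
#' @param trace A [synthesize_trace()] result.
#' @param path Output path without extension; writes `<path>_trace.csv` and
#'   `<path>_events.csv`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "difc_trace"))
  n <- length(trace$ch1)
  write.csv(data.frame(time_s = (seq_len(n) - 1L) / trace$fs,
                       ch1 = trace$ch1, ch2 = trace$ch2),
            paste0(path, "_trace.csv"), row.names = FALSE)
  write.csv(trace$events, paste0(path, "_events.csv"), row.names = FALSE)
  invisible(path)
}

#' Depth profiles of a sweep as one tidy table
#'
#' @param profiles Named list (by SDS) of lists (by wavelength) of
#'   [midline_depth_profile()] objects, or a flat named list.
#' @return A data frame with columns `wavelength_nm`, `sds_mm`, `depth_mm`,
#'   `value`, `normalization`.
#' @export
profiles_table <- function(profiles) {
  flat <- list()
  walk <- function(p) {
    if (inherits(p, "depth_profile")) {
      flat[[length(flat) + 1L]] <<- p
    } else if (is.list(p)) {
      lapply(p, walk)
    }
  }
  walk(profiles)
  do.call(rbind, lapply(flat, function(p) {
    data.frame(wavelength_nm = attr(p, "wavelength_nm"),
               sds_mm = attr(p, "sds_mm"),
               depth_mm = p$depth_mm, value = p$value,
               normalization = attr(p, "normalization"))
  }))
}

#' Run the full modeling study end to end
#'
#' Chains the package's modules into the standard report: per-wavelength
#' SDS sweeps of the Born sensitivity with midline profiles, depth-of-
#' maximum and peak-sensitivity summaries; calibrated contrast curves with
#' maximum detection depths and SDS-optimization tables; optical-property
#' and brightness robustness sweeps; irradiance checks; and a synthetic
#' flow-phantom depth sweep run through the peak-detection pipeline.
#' Writes tidy CSV tables plus a machine-readable `summary.json` (stamped
#' with the configuration hash and seed) into `config$out_dir`.
#'
#' @param config A [difc_run_config()].  Scale `n_photons`,
#'   `phantom$duration_s` and the grids down for interactive use.
#' @param dry_run If `TRUE`, return the stage plan without computing.
#' @return Invisibly, a list with the main tables (`profiles`,
#'   `depth_summary`, `contrast`, `detection_depths`, `sds_optimum`,
#'   `property_robustness`, `brightness_robustness`, `irradiance`,
#'   `phantom_counts`, `false_alarm`).
#' @export
reproduce_study <- function(config = difc_run_config(), dry_run = FALSE) {
  stopifnot(inherits(config, "difc_run_config"))
  stages <- c("jacobian-sweep", "contrast-curves", "sds-optimization",
              "property-robustness", "brightness-robustness",
              "irradiance", "phantom-synthesis", "false-alarm")
  if (dry_run) return(stages)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = config_hash(config), seed = config$seed,
                package_version = as.character(utils::packageVersion("difcsim")))
  emit <- function(df, name) {
    path <- file.path(config$out_dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# difcsim %s config %s seed %d",
                       stamp$package_version, stamp$config_hash, stamp$seed),
               con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }

  volume <- voxel_volume(config$volume_extent_mm, config$voxel_size_mm)
  mc <- mc_config(config$n_photons, config$time_gate_ns, config$seed)
  model0 <- detection_model(noise_fraction = config$noise_fraction,
                            baseline_fraction = config$baseline_fraction,
                            threshold_multiple = config$threshold_multiple)
  depth_grid <- seq(config$voxel_size_mm, 5, by = config$voxel_size_mm)

  ## stage 1: sensitivity sweeps and midline profiles
  sweeps <- lapply(config$wavelengths, function(wl) {
    cfg <- mc
    cfg$seed <- mc$seed + 100L * match(wl, c("488", "640", "780"))
    sds_sweep(tissue_preset(wl), config$sds_mm, volume, cfg)
  })
  names(sweeps) <- config$wavelengths
  profiles <- lapply(sweeps, function(maps) lapply(maps, midline_depth_profile))
  raw_tab <- profiles_table(profiles)
  norm_all <- normalize_profiles(unlist(profiles, recursive = FALSE))
  norm_tab <- profiles_table(norm_all)
  raw_tab$value_normalized <- norm_tab$value
  raw_tab$normalization <- NULL
  emit(raw_tab, "midline_profiles")

  depth_summary <- do.call(rbind, lapply(names(sweeps), function(wl) {
    do.call(rbind, lapply(names(sweeps[[wl]]), function(s) {
      p <- profiles[[wl]][[s]]
      data.frame(wavelength_nm = as.numeric(wl), sds_mm = as.numeric(s),
                 depth_of_max_mm = depth_of_max_sensitivity(p),
                 max_midline_value = max(p$value))
    }))
  }))
  emit(depth_summary, "depth_of_max_sensitivity")

  ## stage 2: calibrated contrast curves
  anchor <- config$calibration_anchor
  anchor_map <- sweeps[[anchor$wavelength]][[as.character(anchor$sds_mm)]]
  if (is.null(anchor_map)) {
    stop("calibration anchor (", anchor$wavelength, " nm, ", anchor$sds_mm,
         " mm) is not part of the configured sweep")
  }
  model <- calibrate_eta_cell(anchor_map, model0, anchor$depth_mm,
                              depths = depth_grid)
  curves <- lapply(sweeps, function(maps)
    lapply(maps, contrast_curve, model = model, depths = depth_grid))
  contrast_tab <- do.call(rbind, lapply(names(curves), function(wl) {
    do.call(rbind, lapply(names(curves[[wl]]), function(s) {
      cu <- curves[[wl]][[s]]
      data.frame(wavelength_nm = as.numeric(wl), sds_mm = as.numeric(s),
                 depth_mm = cu$depth_mm, snr_db = cu$snr_db)
    }))
  }))
  emit(contrast_tab, "contrast_curves")

  detection_depths <- do.call(rbind, lapply(names(curves), function(wl) {
    do.call(rbind, lapply(names(curves[[wl]]), function(s) {
      data.frame(wavelength_nm = as.numeric(wl), sds_mm = as.numeric(s),
                 max_detection_depth_mm =
                   max_detection_depth(curves[[wl]][[s]], model))
    }))
  }))
  emit(detection_depths, "max_detection_depths")

  ## stage 3: SDS optimization at depth
  opt_wl <- if ("780" %in% names(curves)) "780" else names(curves)[1]
  opt_depths <- c(2, 3, 4)
  opt_depths <- opt_depths[opt_depths <= max(depth_grid)]
  sds_optimum <- data.frame(
    depth_mm = opt_depths,
    best_sds_mm = vapply(opt_depths, function(d)
      sds_argmax_at_depth(curves[[opt_wl]], d), numeric(1L)))
  best_med <- tryCatch(sds_best_median(curves[[opt_wl]], c(2, 4)),
                       error = function(e) NA_real_)
  emit(sds_optimum, "sds_argmax_by_depth")

  ## stages 4-5: robustness
  pert_sds <- intersect(c(0.3, 3), config$sds_mm)
  property_robustness <- property_perturbation_sweep(
    tissue_preset(opt_wl), model, sds_set = pert_sds,
    factors = c(0.5, 1, 1.5), volume = volume, config = mc,
    depths = depth_grid)
  emit(property_robustness, "property_robustness")
  brightness_robustness <- brightness_perturbation_sweep(
    model, curves[[opt_wl]][as.character(pert_sds)])
  emit(brightness_robustness, "brightness_robustness")

  ## stage 6: irradiance
  irr <- do.call(rbind, lapply(c(1, 3), function(d) {
    chk <- irradiance_check(20, d)
    data.frame(power_mW = 20, spot_diameter_mm = d,
               irradiance_mW_cm2 = chk$irradiance_mW_cm2,
               compliant = chk$compliant)
  }))
  emit(irr, "irradiance")

  ## stage 7: synthetic phantom depth sweep through the pipeline
  ph_args <- config$phantom
  ph_depths <- ph_args$depths_mm
  if (is.null(ph_depths)) ph_depths <- c(0.75, 1, 1.5, 2, 3, 4)
  ph_args$depths_mm <- NULL
  phantom_counts <- do.call(rbind, lapply(names(sweeps), function(wl) {
    map <- sweeps[[wl]][[1L]]
    do.call(rbind, lapply(ph_depths, function(d) {
      pc <- do.call(flow_phantom_config,
                    c(list(vessel_depth_mm = d, seed = config$seed),
                      ph_args))
      tr <- synthesize_trace(map, model, pc)
      res <- detect_events(tr)
      data.frame(wavelength_nm = as.numeric(wl), depth_mm = d,
                 true_events = nrow(tr$events),
                 candidates_ch1 = sum(!res$candidates1$boundary),
                 matched = nrow(res$matches),
                 rate_per_min = nrow(res$matches) / (pc$duration_s / 60))
    }))
  }))
  emit(phantom_counts, "phantom_detection_counts")

  ## stage 8: false alarm control
  fa_cfg <- do.call(flow_phantom_config,
                    c(list(vessel_depth_mm = 1, seed = config$seed + 9000L),
                      ph_args))
  fa <- false_alarm_rate(lapply(1:5, function(i) {
    cfg_i <- fa_cfg
    cfg_i$seed <- fa_cfg$seed + i
    noise_only_trace(model, cfg_i)
  }))

  summary <- c(stamp, list(
    snr_floor_db = model$snr_floor_db,
    calibrated_eta_cell = model$eta_cell,
    calibration_anchor = anchor,
    sds_argmax = as.list(stats::setNames(sds_optimum$best_sds_mm,
                                         paste0("depth_", sds_optimum$depth_mm, "mm"))),
    sds_best_median_2_4mm = best_med,
    max_property_depth_shift_mm = max(abs(property_robustness$delta_mm)),
    max_brightness_depth_shift_mm = max(abs(brightness_robustness$delta_mm)),
    irradiance_20mW_3mm = irr$irradiance_mW_cm2[irr$spot_diameter_mm == 3],
    false_alarm_per_min = fa$single_channel_rate_per_min))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(profiles = raw_tab, depth_summary = depth_summary,
                 contrast = contrast_tab,
                 detection_depths = detection_depths,
                 sds_optimum = sds_optimum,
                 property_robustness = property_robustness,
                 brightness_robustness = brightness_robustness,
                 irradiance = irr, phantom_counts = phantom_counts,
                 false_alarm = fa, model = model))
}
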