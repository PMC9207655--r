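#' Flow-phantom configuration for synthetic DiFC traces
#'
#' Describes the emulated flow-phantom experiment: fluorescent microspheres
#' suspended at a known concentration are pumped through microbore tubing
#' embedded at a fixed depth, while two probes read the diffuse fluorescence
#' at the surface.  The mean flow speed is derived from the volumetric rate
#' and the tube cross-section (`flow_speed()`), about 16.4 mm/s at the
#' defaults.
#'
#' @param concentration_per_ml Particles per milliliter (default 1000).
#' @param flow_rate_ul_min Volumetric flow, microliters per minute
#'   (default 50).
#' @param tube_inner_diameter_mm Tube inner diameter, mm (default 0.254,
#'   the nominal ID of the microbore tubing emulated).
#' @param vessel_depth_mm Depth of the tube below the surface, mm.
#' @param probe_separation_mm Distance between the two probes' fields along
#'   the flow direction, mm (default 3).
#' @param duration_s Trace duration, s (default 60).
#' @param sampling_rate_hz Sampling rate, Hz (default 2000).
#' @param seed Integer seed for the trace synthesis.
#' @param brightness_cv Coefficient of variation of a log-normal per-event
#'   brightness spread (default 0: all events share `eta_cell`).
#'
#' @return An object of class `"flow_phantom_config"`.
#' @export
flow_phantom_config <- function(concentration_per_ml = 1000,
                                flow_rate_ul_min = 50,
                                tube_inner_diameter_mm = 0.254,
                                vessel_depth_mm = 1,
                                probe_separation_mm = 3,
                                duration_s = 60,
                                sampling_rate_hz = 2000,
                                seed = 1L,
                                brightness_cv = 0) {
  stopifnot(concentration_per_ml >= 0, flow_rate_ul_min > 0,
            tube_inner_diameter_mm > 0, vessel_depth_mm > 0,
            probe_separation_mm > 0, duration_s > 0,
            sampling_rate_hz > 0, brightness_cv >= 0)
  structure(
    list(concentration_per_ml = concentration_per_ml,
         flow_rate_ul_min = flow_rate_ul_min,
         tube_inner_diameter_mm = tube_inner_diameter_mm,
         vessel_depth_mm = vessel_depth_mm,
         probe_separation_mm = probe_separation_mm,
         duration_s = duration_s,
         sampling_rate_hz = sampling_rate_hz,
         seed = as.integer(seed),
         brightness_cv = brightness_cv),
    class = "flow_phantom_config")
}

#' Mean flow speed implied by a phantom configuration
#'
#' Volumetric rate divided by the tube cross-section area.
#'
#' @param config A [flow_phantom_config()].
#' @return Speed in mm/s.
#' @export
flow_speed <- function(config) {
  (config$flow_rate_ul_min / 60) /
    (pi * (config$tube_inner_diameter_mm / 2)^2)
}

# events/s: concentration (ml^-1) x volumetric rate (ml/s)
.event_rate_per_s <- function(config) {
  config$concentration_per_ml * config$flow_rate_ul_min / 1000 / 60
}

#' Simulated cell arrival times
#'
#' Particle arrivals at the probe field form a homogeneous Poisson process
#' with rate concentration x volumetric flow (50 per minute at the
#' defaults).
#'
#' @param config A [flow_phantom_config()]; its `seed` fixes the draw.
#' @return Ordered arrival times in seconds within `[0, duration_s]`.
#' @export
cell_arrival_times <- function(config) {
  stopifnot(inherits(config, "flow_phantom_config"))
  set.seed(config$seed)
  .arrival_times(config)
}

.arrival_times <- function(config) {
  rate <- .event_rate_per_s(config)
  if (rate == 0) return(numeric(0L))
  # draw a comfortable surplus of exponential gaps, extend if short
  t <- cumsum(rexp(ceiling(rate * config$duration_s * 1.5) + 10, rate))
  while (length(t) && t[length(t)] < config$duration_s) {
    t <- c(t, t[length(t)] + cumsum(rexp(10, rate)))
  }
  t[t <= config$duration_s]
}

#' Time-domain pulse of one particle transit
#'
#' As a particle rides the flow through the sensitivity field, the detected
#' peak traces the midline sensitivity along the flow (y) axis at the vessel
#' depth, compressed in time by the flow speed: faster flow gives
#' proportionally narrower pulses.
#'
#' @param map A [born_sensitivity()] map for the probe.
#' @param config A [flow_phantom_config()].
#' @param model A [detection_model()] supplying the cell yield.
#' @return A data frame of class `"peak_waveform"` with columns `t_s`
#'   (centered on the transit midpoint) and `value`
#'   (`eta_cell` x sensitivity), with an `fwhm_s` attribute.
#' @export
peak_waveform <- function(map, config, model) {
  stopifnot(inherits(map, "sensitivity_map"),
            inherits(config, "flow_phantom_config"),
            inherits(model, "detection_model"))
  h <- map$volume$voxel_size
  iz <- .depth_layer(config$vessel_depth_mm, h, dim(map$W)[3L])
  mid <- (map$source_position + map$detector_position) / 2
  ix <- .columns_at(mid[1], h, dim(map$W)[1L])
  w_y <- apply(map$W[ix, , iz, drop = FALSE], 2L, mean)
  y <- (seq_along(w_y) - 0.5) * h
  v <- flow_speed(config)
  t_s <- (y - map$volume$extent[2] / 2) / v
  out <- structure(
    data.frame(t_s = t_s, value = model$eta_cell * w_y),
    class = c("peak_waveform", "data.frame"))
  attr(out, "fwhm_s") <- .fwhm_of(t_s, out$value)
  out
}

# FWHM of a sampled unimodal pulse, linear interpolation at half maximum
.fwhm_of <- function(t, v) {
  if (all(v <= 0)) return(NA_real_)
  ipk <- which.max(v)
  half <- v[ipk] / 2
  left <- NA_real_; right <- NA_real_
  i <- ipk
  while (i > 1L && v[i - 1L] > half) i <- i - 1L
  if (i > 1L) {
    left <- t[i - 1L] + (t[i] - t[i - 1L]) * (half - v[i - 1L]) / (v[i] - v[i - 1L])
  }
  j <- ipk
  n <- length(v)
  while (j < n && v[j + 1L] > half) j <- j + 1L
  if (j < n) {
    right <- t[j] + (t[j + 1L] - t[j]) * (half - v[j]) / (v[j + 1L] - v[j])
  }
  right - left
}

#' Synthesize a two-probe DiFC trace with ground truth
#'
#' Builds the two detector channels sample by sample: a constant background
#' at `baseline_fraction` of full scale (full scale = 1), one transit pulse
#' per Poisson arrival (shape from [peak_waveform()], scaled so the modeled
#' SNR of the contrast model carries over exactly), and additive Gaussian
#' noise of standard deviation `noise_fraction` x background.  The second
#' probe sees each event delayed by `probe_separation_mm / flow speed`.
#' A ground-truth event log (arrival time, depth, per-probe true amplitude)
#' is attached.
#'
#' @param map A [born_sensitivity()] map shared by both (identical) probes,
#'   or `NULL` for an event-free trace (requires zero concentration).
#' @param model A [detection_model()].
#' @param config A [flow_phantom_config()].
#' @return An object of class `"difc_trace"`: list with `ch1`, `ch2`
#'   (numeric vectors), `fs`, `duration_s`, `baseline`, `events` (data
#'   frame: `time_s`, `time2_s`, `depth_mm`, `amplitude`), `config`,
#'   `model`.
#' @export
synthesize_trace <- function(map, model, config) {
  stopifnot(inherits(model, "detection_model"),
            inherits(config, "flow_phantom_config"))
  fs <- config$sampling_rate_hz
  n <- round(config$duration_s * fs)
  baseline <- model$baseline_fraction
  sigma <- model$noise_fraction * baseline
  set.seed(config$seed)

  if (is.null(map)) {
    if (config$concentration_per_ml > 0) {
      stop("a sensitivity map is required when the concentration is nonzero")
    }
    events <- data.frame(time_s = numeric(0L), time2_s = numeric(0L),
                         depth_mm = numeric(0L), amplitude = numeric(0L))
    ch1 <- baseline + rnorm(n, 0, sigma)
    ch2 <- baseline + rnorm(n, 0, sigma)
    return(structure(list(ch1 = ch1, ch2 = ch2, fs = fs,
                          duration_s = config$duration_s,
                          baseline = baseline, events = events,
                          config = config, model = model),
                     class = "difc_trace"))
  }

  stopifnot(inherits(map, "sensitivity_map"))
  # detector gain pinning the homogeneous background at baseline_fraction
  gain <- baseline / background_signal(map, model)
  wf <- peak_waveform(map, config, model)
  fwhm <- attr(wf, "fwhm_s")
  if (is.finite(fwhm) && fs * fwhm < 10) {
    warning("sampling rate resolves fewer than 10 samples per pulse FWHM")
  }
  arrivals <- .arrival_times(config)
  bf <- if (config$brightness_cv > 0) {
    sdlog <- sqrt(log(1 + config$brightness_cv^2))
    rlnorm(length(arrivals), -sdlog^2 / 2, sdlog)
  } else {
    rep_len(1, length(arrivals))
  }
  delay <- config$probe_separation_mm / flow_speed(config)

  tt <- (seq_len(n) - 1L) / fs
  sig1 <- numeric(n)
  sig2 <- numeric(n)
  amp1 <- numeric(length(arrivals))   # realized (sampled) peak amplitude
  for (k in seq_along(arrivals)) {
    for (probe in 1:2) {
      t0 <- arrivals[k] + if (probe == 2L) delay else 0
      tq <- wf$t_s + t0
      i0 <- max(1L, ceiling(tq[1L] * fs) + 1L)
      i1 <- min(n, floor(tq[length(tq)] * fs) + 1L)
      if (i1 < i0) next
      idx <- i0:i1
      pv <- approx(tq, wf$value, xout = tt[idx], rule = 1)$y
      pv[is.na(pv)] <- 0
      if (probe == 1L) {
        sig1[idx] <- sig1[idx] + gain * bf[k] * pv
        amp1[k] <- gain * bf[k] * max(pv)
      } else {
        sig2[idx] <- sig2[idx] + gain * bf[k] * pv
      }
    }
  }
  events <- data.frame(time_s = arrivals,
                       time2_s = arrivals + delay,
                       depth_mm = config$vessel_depth_mm,
                       amplitude = amp1)
  ch1 <- baseline + sig1 + rnorm(n, 0, sigma)
  ch2 <- baseline + sig2 + rnorm(n, 0, sigma)
  structure(list(ch1 = ch1, ch2 = ch2, fs = fs,
                 duration_s = config$duration_s,
                 baseline = baseline, events = events,
                 config = config, model = model),
            class = "difc_trace")
}

#' Event-free control trace
#'
#' [synthesize_trace()] with the particle concentration forced to zero:
#' pure background plus instrument noise on both channels, emulating the
#' buffer-only control runs used to measure the false alarm rate.
#'
#' @param model A [detection_model()].
#' @param config A [flow_phantom_config()]; the concentration is ignored.
#' @return A `"difc_trace"` with an empty event log.
#' @export
noise_only_trace <- function(model, config) {
  config$concentration_per_ml <- 0
  synthesize_trace(NULL, model, config)
}

#' @export
print.difc_trace <- function(x, ...) {
  cat(sprintf("DiFC trace: 2 channels, %.0f s at %g Hz, %d ground-truth events\n",
              x$duration_s, x$fs, nrow(x$events)))
  cat(sprintf("  baseline %.3g, depth %g mm, seed %d\n",
              x$baseline, x$config$vessel_depth_mm, x$config$seed))
  invisible(x)
}

#' @export
plot.difc_trace <- function(x, max_points = 20000L, ...) {
  n <- length(x$ch1)
  idx <- if (n > max_points) round(seq(1L, n, length.out = max_points)) else seq_len(n)
  t <- (idx - 1L) / x$fs
  graphics::plot(t, x$ch1[idx], type = "l", xlab = "time (s)",
                 ylab = "output (full scale = 1)", ...)
  graphics::lines(t, x$ch2[idx], col = "grey50")
  if (nrow(x$events)) {
    graphics::abline(v = x$events$time_s, col = "red", lty = 3)
  }
  invisible(x)
}
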