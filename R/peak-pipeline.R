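#' Moving-median background subtraction
#'
#' Removes the slowly varying background (autofluorescence and drift) by
#' subtracting a centered running median; the median is robust to the brief
#' transits of single cells, so peaks ride through essentially unchanged.
#' Edge windows shrink symmetrically (no wrap-around).
#'
#' @param x Numeric channel samples.
#' @param fs Sampling rate, Hz.
#' @param window_s Median window length, s (default 5).
#' @return The background-subtracted channel (same length).
#' @export
moving_median_subtract <- function(x, fs, window_s = 5) {
  if (!length(x)) stop("empty channel")
  k <- round(window_s * fs)
  if (k < 3) stop("median window must span at least 3 samples")
  if (k %% 2 == 0) k <- k + 1
  x - .rolling_median_cpp(as.numeric(x), as.integer(k))
}

#' Windowed robust noise estimate
#'
#' Local noise scale of a background-subtracted channel: the median absolute
#' deviation times 1.4826 (the Gaussian consistency constant) over a
#' centered moving window, truncated at the trace edges.  For speed the
#' estimate is evaluated every `stride_s` seconds and linearly interpolated
#' in between (set `stride_s = 1/fs` for the exact per-sample estimate).
#' A plain standard deviation is available via `method = "sd"`.
#'
#' @param x Background-subtracted samples.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, s (default 60).
#' @param stride_s Evaluation stride, s (default 1).
#' @param method `"mad"` (default, outlier-robust) or `"sd"`.
#' @return Per-sample noise estimate (same length as `x`).
#' @export
local_noise <- function(x, fs, window_s = 60, stride_s = 1,
                        method = c("mad", "sd")) {
  method <- match.arg(method)
  if (!length(x)) stop("empty channel")
  w <- round(window_s * fs)
  if (w < 30) stop("noise window must span at least 30 samples")
  stride <- max(1L, round(stride_s * fs))
  if (method == "mad") {
    return(.rolling_mad_cpp(x, as.integer(w), as.integer(stride)))
  }
  n <- length(x)
  centers <- unique(c(seq(1L, n, by = stride), n))
  half <- w %/% 2
  vals <- vapply(centers, function(c) {
    lo <- max(1L, c - half); hi <- min(n, c + half)
    stats::sd(x[lo:hi])
  }, numeric(1L))
  approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Centered moving-average pre-filter
#'
#' Short boxcar smoothing applied before thresholding; edge windows
#' truncate.
#'
#' @param x Numeric samples.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length, s (default 0.020).
#' @return Smoothed samples.
#' @export
moving_average <- function(x, fs, window_s = 0.020) {
  n <- length(x)
  k <- max(1L, round(window_s * fs))
  if (k == 1L || n == 0L) return(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k - 1L - half_lo
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - half_lo)
  hi <- pmin(n, seq_len(n) + half_hi)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Threshold-crossing peak candidates
#'
#' After the moving-average pre-filter, every maximal contiguous excursion
#' of the signal above `threshold_multiple` times the local noise yields
#' exactly one candidate at its maximum.  Candidate amplitude is the
#' excursion maximum, width the full width at half maximum (linear
#' interpolation), and the SNR in dB is recorded; every emitted candidate
#' clears the `20 log10(threshold_multiple)` floor by construction.
#' Excursions touching the first or last sample are flagged (`boundary`)
#' so rate statistics can exclude them.
#'
#' @param x Background-subtracted channel.
#' @param noise Per-sample noise estimate (from [local_noise()]).
#' @param fs Sampling rate, Hz.
#' @param threshold_multiple Detection threshold in noise units (default 5).
#' @param prefilter_s Moving-average window, s (default 0.020; 0 disables).
#' @param channel Optional channel label stored with the candidates.
#' @return A data frame of class `"peak_candidates"`: `time_s`,
#'   `amplitude`, `width_s`, `snr_db`, `channel`, `boundary`.
#' @export
find_peak_candidates <- function(x, noise, fs, threshold_multiple = 5,
                                 prefilter_s = 0.020, channel = NA_integer_) {
  stopifnot(length(x) == length(noise))
  f <- if (prefilter_s > 0) moving_average(x, fs, prefilter_s) else x
  above <- f > threshold_multiple * noise
  empty <- data.frame(time_s = numeric(0L), amplitude = numeric(0L),
                      width_s = numeric(0L), snr_db = numeric(0L),
                      channel = integer(0L), boundary = logical(0L))
  class(empty) <- c("peak_candidates", "data.frame")
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  n <- length(x)
  rows <- lapply(seq_along(starts), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    seg <- f[i0:i1]
    ipk <- i0 + which.max(seg) - 1L
    amp <- f[ipk]
    # FWHM on the filtered signal around the peak
    half <- amp / 2
    li <- ipk
    while (li > 1L && f[li - 1L] > half) li <- li - 1L
    tl <- if (li == 1L) 1 else
      (li - 1L) + (half - f[li - 1L]) / (f[li] - f[li - 1L])
    ri <- ipk
    while (ri < n && f[ri + 1L] > half) ri <- ri + 1L
    tr <- if (ri == n) n else
      ri + (half - f[ri]) / (f[ri + 1L] - f[ri])
    data.frame(time_s = (ipk - 1L) / fs,
               amplitude = amp,
               width_s = (tr - tl) / fs,
               snr_db = 20 * log10(amp / noise[ipk]),
               channel = channel,
               boundary = (i0 == 1L || i1 == n))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("peak_candidates", "data.frame")
  out
}

#' Two-probe candidate matching
#'
#' Greedy one-to-one matching of peak candidates between the upstream and
#' downstream probes.  A pair matches when the absolute transit time lies
#' within `transit_window` times the prior `separation / speed`, and the
#' amplitude and width ratios lie within `ratio_window` (factor window,
#' both directions).  Candidates are paired in time order; among admissible
#' partners the one whose transit deviates least from the prior wins.  The
#' transit-time sign sets the flow direction (`forward` when the event
#' reaches probe A first).  Unmatched candidates are returned as discarded.
#'
#' @param a,b Candidate data frames from [find_peak_candidates()] for the
#'   two probes (time-sorted).
#' @param separation_mm Probe separation along the flow, mm.
#' @param speed_mm_s Flow-speed prior, mm/s.
#' @param transit_window Admissible transit-time multiples of the prior
#'   (default `c(0.25, 4)`).
#' @param ratio_window Admissible amplitude/width factor (default 3).
#' @return A list with `matches` (data frame: `time_a_s`, `time_b_s`,
#'   `transit_s`, `direction`, `amplitude_a`, `amplitude_b`, `width_a_s`,
#'   `width_b_s`), `discarded_a`, `discarded_b`.
#' @export
match_candidates <- function(a, b, separation_mm, speed_mm_s,
                             transit_window = c(0.25, 4),
                             ratio_window = 3) {
  prior <- separation_mm / speed_mm_s
  lo <- transit_window[1] * prior
  hi <- transit_window[2] * prior
  used_b <- rep_len(FALSE, nrow(b))
  rows <- list()
  for (i in seq_len(nrow(a))) {
    dt <- b$time_s - a$time_s[i]
    ok <- !used_b & abs(dt) >= lo & abs(dt) <= hi &
      b$amplitude / a$amplitude[i] <= ratio_window &
      a$amplitude[i] / b$amplitude <= ratio_window &
      b$width_s / a$width_s[i] <= ratio_window &
      a$width_s[i] / b$width_s <= ratio_window
    if (!any(ok)) next
    j <- which(ok)[which.min(abs(abs(dt[ok]) - prior))]
    used_b[j] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      time_a_s = a$time_s[i], time_b_s = b$time_s[j],
      transit_s = dt[j],
      direction = if (dt[j] > 0) "forward" else "reverse",
      amplitude_a = a$amplitude[i], amplitude_b = b$amplitude[j],
      width_a_s = a$width_s[i], width_b_s = b$width_s[j])
  }
  matched_a <- if (length(rows)) {
    vapply(rows, function(r) r$time_a_s, numeric(1L))
  } else numeric(0L)
  list(matches = if (length(rows)) do.call(rbind, rows) else
         data.frame(time_a_s = numeric(0L), time_b_s = numeric(0L),
                    transit_s = numeric(0L), direction = character(0L),
                    amplitude_a = numeric(0L), amplitude_b = numeric(0L),
                    width_a_s = numeric(0L), width_b_s = numeric(0L)),
       discarded_a = a[!a$time_s %in% matched_a, , drop = FALSE],
       discarded_b = b[!used_b, , drop = FALSE])
}

#' Run the full detection pipeline on one trace
#'
#' Background subtraction, noise estimation, peak-candidate search on both
#' channels, and two-probe matching with the transit prior taken from the
#' trace's flow configuration.
#'
#' @param trace A [synthesize_trace()] result (or compatible list).
#' @param median_window_s,noise_window_s,threshold_multiple,prefilter_s
#'   Pipeline parameters (defaults 5 s, 60 s, 5, 0.020 s).
#' @param noise_stride_s Noise-evaluation stride, s (default 1).
#' @return A list with `candidates1`, `candidates2`, `matches`,
#'   `discarded_a`, `discarded_b`.
#' @export
detect_events <- function(trace, median_window_s = 5, noise_window_s = 60,
                          threshold_multiple = 5, prefilter_s = 0.020,
                          noise_stride_s = 1) {
  stopifnot(inherits(trace, "difc_trace"))
  run <- function(x, id) {
    s <- moving_median_subtract(x, trace$fs, median_window_s)
    nz <- local_noise(s, trace$fs, noise_window_s, noise_stride_s)
    find_peak_candidates(s, nz, trace$fs, threshold_multiple, prefilter_s,
                         channel = id)
  }
  c1 <- run(trace$ch1, 1L)
  c2 <- run(trace$ch2, 2L)
  m <- match_candidates(c1, c2, trace$config$probe_separation_mm,
                        flow_speed(trace$config))
  list(candidates1 = c1, candidates2 = c2,
       matches = m$matches, discarded_a = m$discarded_a,
       discarded_b = m$discarded_b)
}

#' False alarm rate on event-free traces
#'
#' Runs the single-channel pipeline over a set of control traces and
#' reports candidates per minute (boundary-touching excursions excluded).
#' When traces carry two channels, the matched-pair false rate is reported
#' as well.
#'
#' @param traces A list of event-free `"difc_trace"` objects.
#' @param ... Pipeline parameters passed to [detect_events()].
#' @return A list with `single_channel_rate_per_min`,
#'   `matched_rate_per_min`, `n_minutes` (per channel), `n_candidates`.
#' @export
false_alarm_rate <- function(traces, ...) {
  if (inherits(traces, "difc_trace")) traces <- list(traces)
  tot_min <- 0
  n_cand <- 0
  n_match <- 0
  for (tr in traces) {
    res <- detect_events(tr, ...)
    keep1 <- !res$candidates1$boundary
    keep2 <- !res$candidates2$boundary
    n_cand <- n_cand + sum(keep1) + sum(keep2)
    n_match <- n_match + nrow(res$matches)
    tot_min <- tot_min + tr$duration_s / 60
  }
  list(single_channel_rate_per_min = n_cand / (2 * tot_min),
       matched_rate_per_min = n_match / tot_min,
       n_minutes = tot_min, n_candidates = n_cand)
}
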