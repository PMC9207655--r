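test_that("moving-median subtraction removes background, spares peaks", {
  fs <- 2000
  flat <- rep(3.7, 8000)
  expect_equal(moving_median_subtract(flat, fs, 1), rep(0, 8000))

  # a 50-ms pulse rides through a 5-s median essentially unchanged
  x <- rep(1, 2000 * 12)
  pulse <- exp(-((seq_len(200) - 100) / 30)^2)
  x[12000:12199] <- x[12000:12199] + pulse
  sub <- moving_median_subtract(x, fs, 5)
  expect_lt(abs(max(sub) - max(pulse)) / max(pulse), 0.01)

  # offset invariance, checked against a brute-force median oracle
  set.seed(2)
  y <- rnorm(1000)
  k <- 101
  oracle <- y - naive_moving_median(y, k)
  got <- moving_median_subtract(y, fs = 1, window_s = k)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(moving_median_subtract(y + 5, 1, k), got, tolerance = 1e-12)

  expect_error(moving_median_subtract(numeric(0), fs, 5), "empty")
  expect_error(moving_median_subtract(y, 1, 2), "3 samples")

  # idempotence on constant-background traces
  once <- moving_median_subtract(x, fs, 5)
  twice <- moving_median_subtract(once, fs, 5)
  expect_lt(max(abs(twice - once)), 1e-12)
})

test_that("windowed MAD recovers the noise scale robustly", {
  set.seed(9)
  fs <- 2000
  sigma <- 0.3
  x <- rnorm(1e5, 0, sigma)
  est <- local_noise(x, fs, window_s = 60, stride_s = 1)
  expect_lt(max(abs(est / sigma - 1)), 0.03)

  # one isolated large peak occupying < 1% of the window barely moves it
  xp <- x
  xp[50000:50400] <- xp[50000:50400] + 50 * sigma
  estp <- local_noise(xp, fs, window_s = 60, stride_s = 1)
  expect_lt(max(abs(estp / est - 1)), 0.02)

  expect_equal(local_noise(rep(0, 5000), fs, 2), rep(0, 5000))
  expect_error(local_noise(numeric(0), fs), "empty")
  expect_error(local_noise(x, fs, window_s = 0.01), "30 samples")

  # the plain-sd variant agrees on clean Gaussian noise
  est_sd <- local_noise(x, fs, window_s = 60, stride_s = 1, method = "sd")
  expect_lt(max(abs(est_sd / sigma - 1)), 0.03)
})

test_that("moving average matches the convolution oracle away from edges", {
  set.seed(3)
  x <- rnorm(500)
  k <- 9
  got <- moving_average(x, fs = 1, window_s = k)
  oracle <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  inner <- (k + 1):(500 - k)
  expect_equal(got[inner], oracle[inner], tolerance = 1e-12)
})

test_that("peak candidates mark one maximum per threshold excursion", {
  fs <- 2000
  expect_equal(nrow(find_peak_candidates(rep(0, 4000), rep(1, 4000), fs)), 0)

  # an 8-sigma Gaussian pulse on Gaussian noise is found at the right time
  hits <- 0
  for (seed in 1:25) {
    set.seed(seed)
    sigma <- 0.01
    n <- 20000
    x <- rnorm(n, 0, sigma)
    tpk <- 9000
    pulse <- 8 * sigma * exp(-((seq_len(n) - tpk) / (0.03 * fs))^2)
    x <- x + pulse
    nz <- local_noise(x, fs, window_s = 10, stride_s = 0.5)
    cand <- find_peak_candidates(x, nz, fs)
    # timing jitter of the argmax of a smoothed 50-ms pulse is a few ms
    if (nrow(cand) == 1 &&
        abs(cand$time_s - (tpk - 1) / fs) <= 25 / fs) hits <- hits + 1
  }
  expect_gte(hits, 24)

  # two pulses > 3 FWHM apart resolve; overlapping ones merge
  sigma <- 0.01
  base <- rep(0, 20000)
  nz <- rep(sigma, 20000)
  shape <- function(center, w) exp(-((seq_len(20000) - center) / w)^2)
  two <- 10 * sigma * (shape(8000, 60) + shape(12000, 60))
  expect_equal(nrow(find_peak_candidates(base + two, nz, fs)), 2)
  merged <- 10 * sigma * (shape(9000, 60) + shape(9080, 60))
  expect_equal(nrow(find_peak_candidates(base + merged, nz, fs)), 1)

  # every emitted candidate clears the 13.9-dB floor by construction
  set.seed(11)
  noisy <- rnorm(60000, 0, sigma) + 12 * sigma * shape(30000, 60)
  cand <- find_peak_candidates(noisy, local_noise(noisy, fs, 10), fs)
  expect_true(all(cand$snr_db >= 20 * log10(5) - 1e-9))
})

test_that("two-probe matching pairs forward transits and flags reversals", {
  a <- data.frame(time_s = c(1, 5, 9), amplitude = c(1, 2, 1.5),
                  width_s = c(0.05, 0.05, 0.05), snr_db = 20,
                  channel = 1L, boundary = FALSE)
  b <- a
  b$time_s <- a$time_s + 0.2       # forward transit 0.2 s
  res <- match_candidates(a, b, separation_mm = 3, speed_mm_s = 15)
  expect_equal(nrow(res$matches), 3)
  expect_true(all(res$matches$direction == "forward"))
  expect_equal(res$matches$transit_s, rep(0.2, 3))
  expect_equal(nrow(res$discarded_a), 0)

  # reversed flow: candidate arrives on probe B first
  res_r <- match_candidates(b, a, separation_mm = 3, speed_mm_s = 15)
  expect_true(all(res_r$matches$direction == "reverse"))

  # empty partner list discards everything
  empty <- a[0, ]
  res_e <- match_candidates(a, empty, 3, 15)
  expect_equal(nrow(res_e$matches), 0)
  expect_equal(nrow(res_e$discarded_a), 3)

  # amplitude ratio outside the factor-3 window blocks the pair
  b_big <- b
  b_big$amplitude <- a$amplitude * 4
  res_b <- match_candidates(a, b_big, 3, 15)
  expect_equal(nrow(res_b$matches), 0)

  # conservation: matched + discarded = total
  expect_equal(nrow(res$matches) + nrow(res$discarded_a), nrow(a))
})

test_that("pipeline recovers and matches nearly all synthetic events", {
  map <- fixture_map("780", 0.3, 1e5, seed = 40)
  m <- calibrate_eta_cell(map, unit_model(), 2, estimator = "radial")
  cfg <- flow_phantom_config(vessel_depth_mm = 0.75, duration_s = 60,
                             seed = 8, concentration_per_ml = 800)
  tr <- synthesize_trace(map, m, cfg)
  expect_gte(nrow(tr$events), 15)
  res <- detect_events(tr)
  expect_true(all(res$matches$direction == "forward"))
  delay <- cfg$probe_separation_mm / flow_speed(cfg)
  # the bulk of the transits sit within a few samples of the true lag;
  # occasional overlapping events can pair off-center
  expect_lte(quantile(abs(res$matches$transit_s - delay), 0.9), 0.01)

  # isolated interior events (well separated, away from the trace edges)
  # are recovered and matched essentially always
  ev <- tr$events
  gap <- pmin(c(Inf, diff(ev$time_s)), c(diff(ev$time_s), Inf))
  iso <- ev$time_s > 2 & ev$time_s < cfg$duration_s - 2 & gap > 0.5
  expect_gte(sum(iso), 10)
  hit <- vapply(ev$time_s, function(t0)
    any(abs(res$matches$time_a_s - t0) < 0.05), logical(1L))
  expect_gte(sum(hit[iso]) / sum(iso), 0.95)

  # detected amplitudes of isolated events track ground truth
  # (slope through origin ~ 1); a short pre-filter keeps boxcar
  # attenuation out of the comparison
  res2 <- detect_events(tr, prefilter_s = 0.004)
  truth <- ev$amplitude[iso]
  got <- vapply(ev$time_s[iso], function(t0) {
    i <- which.min(abs(res2$candidates1$time_s - t0))
    if (length(i) && abs(res2$candidates1$time_s[i] - t0) < 0.05)
      res2$candidates1$amplitude[i] else NA_real_
  }, numeric(1L))
  ok <- !is.na(got)
  slope <- sum(got[ok] * truth[ok]) / sum(truth[ok]^2)
  expect_lt(abs(slope - 1), 0.05)
})

test_that("false alarms on clean controls are rare and threshold-monotone", {
  m <- unit_model()
  traces <- lapply(1:3, function(s)
    noise_only_trace(m, flow_phantom_config(duration_s = 60, seed = 100 + s)))
  fa5 <- false_alarm_rate(traces)
  fa6 <- false_alarm_rate(traces, threshold_multiple = 6)
  expect_lte(fa6$single_channel_rate_per_min, fa5$single_channel_rate_per_min)
  expect_equal(fa5$n_minutes, 3)

  # noiseless channels yield exactly zero candidates
  quiet <- traces[[1]]
  quiet$ch1 <- rep(quiet$baseline, length(quiet$ch1))
  quiet$ch2 <- quiet$ch1
  fa0 <- false_alarm_rate(list(quiet))
  expect_equal(fa0$n_candidates, 0)
})
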