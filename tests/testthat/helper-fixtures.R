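# Shared Monte Carlo fixtures, built once per test run and cached.
# Small 20-mm domain keeps runs fast while preserving the 0.25-mm voxel
# pitch used everywhere else.

.fixtures <- new.env(parent = emptyenv())

small_volume <- function(extent = 20) voxel_volume(extent, 0.25)

fixture_map <- function(wl = "780", sds = 0.3, n_photons = 1e5, seed = 42,
                        extent = 20) {
  key <- paste(wl, sds, n_photons, seed, extent, sep = "|")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- sds_sweep(tissue_preset(wl), sds,
                                  small_volume(extent),
                                  mc_config(n_photons, seed = seed))[[1L]]
  }
  .fixtures[[key]]
}

fixture_field <- function(wl = "780", n_photons = 5e4, seed = 42,
                          extent = 20, sds = 0.3) {
  key <- paste("field", wl, n_photons, seed, extent, sds, sep = "|")
  if (is.null(.fixtures[[key]])) {
    vol <- small_volume(extent)
    pr <- probe_positions(vol, sds)
    .fixtures[[key]] <- simulate_fluence(vol, tissue_preset(wl), pr$source,
                                         mc_config(n_photons, seed = seed))
  }
  .fixtures[[key]]
}

# closed-form Henyey-Greenstein CDF of cos(theta), independent oracle for
# the sampler
hg_cdf <- function(ct, g) {
  (1 - g^2) / (2 * g) *
    (1 / sqrt(1 + g^2 - 2 * g * ct) - 1 / (1 + g))
}

# hand-rolled centered running median (window truncated at the edges):
# brute-force oracle for the pipeline's background subtraction
naive_moving_median <- function(x, k) {
  half <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    # mirror the symmetric shrinking at the edges
    m <- min(i - lo, hi - i)
    median(x[(i - m):(i + m)])
  }, numeric(1L))
}

# quick synthetic detection model with a unit-yield cell
unit_model <- function(...) detection_model(eta_cell = 1, eta_af = 1, ...)
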