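# difcsim

Monte Carlo detection-depth modeling for diffuse in vivo flow cytometry
(DiFC).

DiFC detects rare fluorescently labeled circulating cells — circulating
tumor cells in particular — directly in blood vessels, using fiber-optic
probes and diffusely scattered laser light. The technique works routinely
in mice, where the interrogated vessels are under 1 mm deep. Translating it
to humans means detecting a *single* cell 2–4 mm deep (the radial artery or
vein in the wrist), through strongly scattering tissue, on top of a much
larger autofluorescence background. `difcsim` is an R package for the
computational side of that question: who can see a cell, how deep, at which
laser wavelength, and with which source–detector separation (SDS).

## What the package computes

* **Photon transport** — a voxelized Monte Carlo simulator
  (`simulate_fluence()`, Rcpp core) for homogeneous tissue cubes:
  weighted packets, Henyey–Greenstein scattering (g = 0.9), continuous
  absorption, Fresnel boundary at the skin surface (n = 1.37), 5-ns time
  gate, Russian roulette, counter-based per-photon RNG substreams
  (bit-reproducible for a given seed). Literature optical properties for
  the 488/640/780-nm DiFC systems ship as presets (`tissue_preset()`).
  Closed-form diffusion-theory solutions (`analytic_fluence()`) serve as
  independent oracles.
* **Fluorescence sensitivity (Jacobian) maps** — the Born-approximation
  sensitivity of a source–detector pair, assembled from two Green's
  functions by the adjoint/reciprocity trick (`born_sensitivity()`,
  `sds_sweep()`), with midline depth profiles, depth-of-maximum summaries
  and a variance-reducing ring-averaged estimator (`radial_green()`).
* **A detection-limit model** — transient cell peak over homogeneous
  autofluorescence, Gaussian instrument noise at 0.2% of the background,
  and a 5× noise (13.9 dB) detection floor (`detection_model()`,
  `contrast_curve()`, `max_detection_depth()`), calibrated against a
  measured phantom detection depth (`calibrate_eta_cell()`), plus the
  study sweeps: SDS optimization at depth, ±50% optical-property and
  brightness robustness, extended-spot (skin-exposure) variants and
  irradiance checks.
* **Synthetic flow-phantom data** — two-probe DiFC time series with
  ground-truth event logs (`synthesize_trace()`, `noise_only_trace()`):
  Poisson microsphere arrivals, transit pulses shaped by the sensitivity
  field and the flow speed, delayed echoes on the downstream probe.
* **The detection pipeline** — moving-median background subtraction,
  windowed MAD noise estimation, 5×-noise peak candidates, and greedy
  two-probe matching with transit/amplitude/width gates
  (`detect_events()`, `false_alarm_rate()`).
* **An end-to-end driver** — `reproduce_study()` chains everything into
  tidy CSV tables and a machine-readable summary from one validated JSON
  configuration (`difc_run_config()`, `load_config()`).

## A worked example

How deep can the near-infrared system see a cell, and which separation is
best for a 3-mm-deep vessel? (Small domain and photon budget so this runs
in under a minute; production settings are `voxel_volume()` /
`mc_config()` defaults.)

```r
library(difcsim)

vol  <- voxel_volume(30, 0.25)          # 30-mm cube, 0.25-mm voxels
maps <- sds_sweep(tissue_preset("780"), c(0.3, 1, 2, 3), vol,
                  mc_config(n_photons = 2e5, seed = 1))

# calibrate the cell yield so the adjacent-fiber probe reaches 3.5 mm
model <- calibrate_eta_cell(maps[["0.3"]], detection_model(),
                            target_depth = 3.5, estimator = "radial")
curves <- lapply(maps, contrast_curve, model = model, estimator = "radial")

sapply(curves, max_detection_depth, model = model)
#>  0.3    1    2    3
#> 3.50 4.00 4.00 4.25

sds_argmax_at_depth(curves, depth = 3)   # best SDS for a 3-mm-deep cell
#> [1] 1
round(sapply(curves, function(cu) cu$snr_db[cu$depth_mm == 3]), 2)
#>   0.3     1     2     3
#> 19.72 23.94 23.90 22.92
```

Under the 3.5-mm calibration anchor the model puts the larger separations'
detection limits at 4 mm and beyond, and for a cell at exactly 3 mm the
1- and 2-mm separations are neck and neck (0.04 dB apart at this quick
photon budget — resolving that pair takes millions of packets; see the
methods vignette), with both clearly ahead of the adjacent-fiber 0.3-mm
geometry. A synthetic flow-phantom trace run through the full pipeline:

```r
cfg <- flow_phantom_config(vessel_depth_mm = 1, duration_s = 60, seed = 2)
tr  <- synthesize_trace(maps[["0.3"]], model, cfg)
res <- detect_events(tr)
c(true_events = nrow(tr$events), matched = nrow(res$matches))
#> true_events     matched
#>          47          39
table(res$matches$direction)
#> forward
#>      39
```

39 of the 47 seeded microsphere transits are detected on both probes and
matched in the forward flow direction; the misses are all pairs of
near-coincident transits (under ~0.2 s apart) whose peaks merge into a
single threshold excursion — the same coincidence loss a real instrument
shows at high event rates.

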