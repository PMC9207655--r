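test_that("Born sensitivity assembly annihilates, validates and records geometry", {
  g1 <- fixture_field("780", n_photons = 2e4)
  g2 <- mirror_field_x(g1)
  W <- born_sensitivity(g1, g2)
  expect_true(all(W$W >= 0))
  expect_equal(W$sds, 0.3, tolerance = 1e-9)
  expect_equal(W$wavelength_nm, 780)

  # zero excitation field annihilates the product
  g0 <- g1
  g0$values[] <- 0
  expect_true(all(born_sensitivity(g0, g2)$W == 0))

  # incompatible grids refuse to combine
  gsmall <- simulate_fluence(voxel_volume(10, 0.5), tissue_preset("780"),
                             c(5, 5, 0), mc_config(1e3, seed = 1))
  expect_error(born_sensitivity(g1, gsmall), "incompatible")
})

test_that("swapping source and detector roles leaves the map unchanged", {
  # reciprocity: two independently seeded runs, roles swapped, must agree
  # within combined MC error on a coarse downsampling
  vol <- small_volume()
  pr <- probe_positions(vol, 2)
  p <- tissue_preset("640")
  ga <- simulate_fluence(vol, p, pr$source, mc_config(1e5, seed = 21))
  gb <- simulate_fluence(vol, p, pr$detector, mc_config(1e5, seed = 22))
  W1 <- born_sensitivity(ga, gb)$W
  W2 <- born_sensitivity(gb, ga)$W
  expect_identical(W1, W2)  # elementwise product is exactly symmetric

  # mirror-symmetry shortcut agrees with an independent detector run
  Wm <- born_sensitivity(ga, mirror_field_x(ga))$W
  block <- function(W) {
    d <- dim(W)
    f <- 8  # 2-mm blocks
    apply(array(W, c(f, d[1] / f, f, d[2] / f, f, d[3] / f)),
          c(2, 4, 6), sum)
  }
  b1 <- block(W1)
  bm <- block(Wm)
  sel <- b1 > max(b1) * 1e-3
  expect_lt(max(abs(bm[sel] / b1[sel] - 1)), 0.35)
})

test_that("adjoint sensitivity equals brute-force reciprocity on a tiny grid", {
  # 10^3-voxel medium: fluence at B from a source at A must equal fluence
  # at A from a source at B; this is the identity the adjoint trick rests on
  vol <- voxel_volume(2.5, 0.25)
  p <- tissue_preset("488")
  det <- c(1.125, 1.125, 0.125)       # voxel center under the detector site
  probes <- list(c(0.625, 0.625, 1.125), c(1.375, 1.375, 1.625),
                 c(1.875, 0.875, 0.875))
  layer <- function(pos) as.integer(floor(pos / 0.25)) + 1L
  n_ph <- 4e4
  adj <- simulate_fluence(vol, p, det, mc_config(n_ph, seed = 5),
                          source_type = "isotropic")
  for (i in seq_along(probes)) {
    fw <- simulate_fluence(vol, p, probes[[i]],
                           mc_config(n_ph, seed = 50 + i),
                           source_type = "isotropic")
    v_adj <- adj$values[t(layer(probes[[i]]))]
    v_fwd <- fw$values[t(layer(det))]
    expect_lt(abs(v_adj / v_fwd - 1), 0.25,
              label = sprintf("reciprocity mismatch at probe voxel %d", i))
  }
})

test_that("midline profiles handle degenerate, normalized and tied cases", {
  # colocated probes: column directly under the common point
  m0 <- fixture_map("780", sds = 0, n_photons = 2e4, seed = 11)
  p0 <- midline_depth_profile(m0)
  expect_true(all(diff(p0$depth_mm) > 0))
  expect_equal(p0$depth_mm[1], 0.125)
  expect_lte(max(p0$depth_mm), 5)

  # renormalizing a profile by its own maximum leaves max exactly 1
  p0$value <- p0$value / max(p0$value)
  expect_identical(max(p0$value), 1)

  # tie-break toward the shallower depth
  tie <- structure(data.frame(depth_mm = c(0.125, 1.125, 1.375, 2.125),
                              value = c(0.2, 0.9, 0.9, 0.1)),
                   normalization = "raw",
                   class = c("depth_profile", "data.frame"))
  expect_equal(depth_of_max_sensitivity(tie), 1.125)
  mono <- tie
  mono$value <- c(1, 0.5, 0.25, 0.1)
  expect_equal(depth_of_max_sensitivity(mono), 0.125)
  zero <- tie
  zero$value <- 0 * zero$value
  expect_error(depth_of_max_sensitivity(zero), "all-zero")
})

test_that("collection normalization uses one global maximum", {
  maps <- list(`0.3` = fixture_map("780", 0.3, 5e4, seed = 12),
               `3`   = fixture_map("780", 3, 5e4, seed = 13))
  profs <- lapply(maps, midline_depth_profile)
  normed <- normalize_profiles(profs)
  expect_equal(max(vapply(normed, function(p) max(p$value), numeric(1L))), 1)
  expect_identical(attr(normed[[1]], "normalization"),
                   "normalized-to-global-max")
  # exactly one value attains 1
  expect_equal(sum(vapply(normed, function(p) sum(p$value == 1), numeric(1L))), 1)
  # single profile: identical to per-profile normalization
  single <- normalize_profiles(profs[1])
  expect_equal(single[[1]]$value, profs[[1]]$value / max(profs[[1]]$value))
  # all-zero collection is an error
  z <- profs
  z[[1]]$value[] <- 0
  z[[2]]$value[] <- 0
  expect_error(normalize_profiles(z), "all-zero")
  # already-normalized input is rejected
  expect_error(normalize_profiles(normed), "raw")
})

test_that("SDS sweeps are deterministic and reduce to single calls", {
  vol <- small_volume()
  cfg <- mc_config(2e4, seed = 31)
  s1 <- sds_sweep(tissue_preset("780"), 1, vol, cfg)
  pr <- probe_positions(vol, 1)
  g <- simulate_fluence(vol, tissue_preset("780"), pr$source, cfg)
  direct <- born_sensitivity(g, mirror_field_x(g))
  expect_identical(s1[[1]]$W, direct$W)
  s2 <- sds_sweep(tissue_preset("780"), 1, vol, cfg)
  expect_identical(s1[[1]]$W, s2[[1]]$W)
  expect_error(sds_sweep(tissue_preset("780"), 25, vol, cfg), "face")
  expect_error(sds_sweep(tissue_preset("780"), numeric(0), vol, cfg),
               "non-empty")
})

test_that("depth of maximum sensitivity grows with SDS, peak value falls", {
  sds_list <- c(0.3, 2, 4)
  maps <- lapply(sds_list, function(s) fixture_map("780", s, 1e5, seed = 40))
  profs <- lapply(maps, midline_depth_profile, estimator = "radial")
  dmax <- vapply(profs, depth_of_max_sensitivity, numeric(1L))
  expect_true(all(diff(dmax) >= 0))
  peak <- vapply(profs, function(p) max(p$value), numeric(1L))
  expect_true(all(diff(peak) < 0))
})

test_that("longer wavelengths retain more sensitivity at depth", {
  # attenuation ordering 780 > 640 > 488 at >= 2 mm depth, fixed SDS
  profs <- lapply(c("488", "640", "780"), function(wl)
    midline_depth_profile(fixture_map(wl, 0.3, 1e5, seed = 40),
                          estimator = "radial"))
  sel <- profs[[1]]$depth_mm >= 2 & profs[[1]]$depth_mm <= 4
  v <- vapply(profs, function(p) mean(p$value[sel]), numeric(1L))
  expect_true(v[3] > v[2] && v[2] > v[1])
})
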