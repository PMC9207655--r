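test_that("optical property constructors validate their domains", {
  p <- optical_properties(0.05, 25, g = 0.9, n = 1.37, wavelength_nm = 488)
  expect_s3_class(p, "optical_properties")
  expect_error(optical_properties(-0.1, 10), "mu_a")
  expect_error(optical_properties(0.1, 0), "mu_s")
  expect_error(optical_properties(0.1, 10, g = 1), "g")
  expect_error(optical_properties(0.1, 10, n = 0.9), "n")
  expect_error(tissue_preset("550"), "available presets")

  # bundled presets carry the literature coefficients used throughout
  expect_equal(tissue_preset("488")[c("mu_a", "mu_s", "g", "n")],
               list(mu_a = 0.05, mu_s = 25, g = 0.9, n = 1.37))
  expect_equal(tissue_preset("640")[c("mu_a", "mu_s")],
               list(mu_a = 0.025, mu_s = 10))
  expect_equal(tissue_preset("780")[c("mu_a", "mu_s")],
               list(mu_a = 0.002, mu_s = 7))
})

test_that("Henyey-Greenstein sampling matches its closed-form law", {
  set.seed(7)
  u <- cbind(runif(1e5), runif(1e5))

  iso <- hg_sample(0, u)
  expect_lt(abs(mean(iso$cos_theta)), 0.02)        # isotropic limit
  expect_true(all(iso$phi >= 0 & iso$phi < 2 * pi))

  s <- hg_sample(0.9, u)
  expect_lt(abs(mean(s$cos_theta) - 0.9), 0.01)    # HG mean cosine equals g

  # empirical CDF against the closed-form HG CDF (independent oracle)
  grid <- seq(-0.95, 0.999, length.out = 200)
  ecdf_v <- ecdf(s$cos_theta)(grid)
  ks <- max(abs(ecdf_v - hg_cdf(grid, 0.9)))
  expect_lt(ks, 0.01)

  expect_error(hg_sample(1, u), "between -1 and 1")
  expect_error(hg_sample(0.5, cbind(1.2, 0.5)), "0, 1")
})

test_that("Fresnel reflectance covers matched media, normal incidence and TIR", {
  expect_equal(fresnel_reflectance(1.37, 1.37, 0.5), 0)
  # hand-evaluated: ((n1 - n2) / (n1 + n2))^2 at normal incidence
  expect_equal(fresnel_reflectance(1.37, 1, 1), (0.37 / 2.37)^2,
               tolerance = 1e-12)
  # beyond the critical angle asin(1/1.37) ~ 46.9 deg
  expect_equal(fresnel_reflectance(1.37, 1, cos(48 * pi / 180)), 1)
  expect_error(fresnel_reflectance(1.37, 1, 0), "cos_incident")
  expect_error(fresnel_reflectance(0.5, 1, 0.5), "refractive")
})

test_that("diffusion-theory fluence behaves analytically", {
  p <- tissue_preset("780")
  musp <- 7 * (1 - 0.9)
  D <- 1 / (3 * (0.002 + musp))
  mueff <- sqrt(3 * 0.002 * (0.002 + musp))
  expect_equal(analytic_fluence(p, r = 5),
               exp(-mueff * 5) / (4 * pi * D * 5), tolerance = 1e-12)

  # fluence vanishes monotonically as absorption grows
  mus_fix <- 10
  f <- vapply(c(0.01, 0.1, 1, 5), function(ma)
    analytic_fluence(optical_properties(ma, mus_fix), r = 3), numeric(1L))
  expect_true(all(diff(f) < 0))

  # semi-infinite solution is zero on the extrapolated-boundary plane
  zb <- extrapolation_depth(p)
  expect_lt(abs(analytic_fluence(p, geometry = "semi-infinite",
                                 rho = 2, z = -zb)), 1e-12)
  expect_error(analytic_fluence(p, r = 0), "r")
})

test_that("every MC run conserves launched packet weight", {
  vol <- small_volume()
  for (wl in c("488", "640", "780")) {
    f <- simulate_fluence(vol, tissue_preset(wl), c(10, 10, 0),
                          mc_config(n_photons = 2e4, seed = 3))
    expect_lt(abs(weight_balance(f) - 1), 1e-6)
    expect_true(all(f$values >= 0))
  }
  # isotropic interior source and infinite medium conserve as well
  f <- simulate_fluence(vol, tissue_preset("640"), c(10, 10, 10),
                        mc_config(n_photons = 1e4, seed = 3),
                        source_type = "isotropic", boundaries = "none")
  expect_lt(abs(weight_balance(f) - 1), 1e-6)
})

test_that("identical seed and configuration reproduce tallies bit for bit", {
  vol <- small_volume()
  cfg <- mc_config(n_photons = 5e3, seed = 99)
  f1 <- simulate_fluence(vol, tissue_preset("780"), c(10, 10, 0), cfg)
  f2 <- simulate_fluence(vol, tissue_preset("780"), c(10, 10, 0), cfg)
  expect_identical(f1$values, f2$values)
  expect_identical(f1$absorbed_weight, f2$absorbed_weight)
  f3 <- simulate_fluence(vol, tissue_preset("780"), c(10, 10, 0),
                         mc_config(n_photons = 5e3, seed = 100))
  expect_false(identical(f1$values, f3$values))
})

test_that("MC invalid inputs error cleanly", {
  vol <- small_volume()
  expect_error(mc_config(n_photons = 0), "n_photons")
  expect_error(voxel_volume(10, -1), "voxel_size")
  expect_error(voxel_volume(10.1, 0.25), "divisible")
  expect_error(simulate_fluence(vol, tissue_preset("780"), c(10, 10, 5),
                                mc_config(1e3)), "z = 0")
  expect_error(simulate_fluence(vol, tissue_preset("780"), c(30, 10, 0),
                                mc_config(1e3)), "outside")
})

test_that("bounded fluence decays monotonically away from the source", {
  f <- fixture_field("640", n_photons = 1e5)
  rg <- radial_green(f)
  # ring-averaged depth profile near the beam axis, beyond 1 mm
  prof <- colMeans(rg$g[1:4, ])
  z <- rg$z
  sel <- z > 1 & z < 8
  expect_true(all(diff(prof[sel]) < 0))
  # lateral decay at fixed shallow depth
  lat <- rg$g[, which.min(abs(z - 1))]
  rsel <- rg$rho > 1 & rg$rho < 8
  expect_true(all(diff(lat[rsel]) < 0))
})

test_that("scattering work tracks the scattering coefficient", {
  # per-photon path length inside the medium times mu_s estimates the mean
  # number of scattering events; 488 nm (mu_s = 25) must far exceed 780 nm
  # (mu_s = 7) on identical geometry
  events <- vapply(c("488", "780"), function(wl) {
    f <- fixture_field(wl, n_photons = 2e4, seed = 8)
    sum(f$values) * f$volume$voxel_size^3 * f$props$mu_s
  }, numeric(1L))
  expect_gt(events[["488"]], events[["780"]])
})

test_that("MC fluence matches the diffusion oracle in an infinite medium", {
  # radii between ~5 and ~15 transport mean free paths per wavelength
  cases <- list(`488` = c(2, 4), `640` = c(4, 8), `780` = c(6, 12))
  vol <- voxel_volume(40, 0.5)
  ctr <- c(20, 20, 20)
  for (wl in names(cases)) {
    p <- tissue_preset(wl)
    n_ph <- if (wl == "780") 1.2e4 else 8e3
    f <- simulate_fluence(vol, p, ctr, mc_config(n_photons = n_ph, seed = 17),
                          source_type = "isotropic", boundaries = "none")
    h <- vol$voxel_size
    cc <- expand.grid(x = (seq_len(80) - 0.5) * h, y = (seq_len(80) - 0.5) * h,
                      z = (seq_len(80) - 0.5) * h)
    r <- sqrt((cc$x - ctr[1])^2 + (cc$y - ctr[2])^2 + (cc$z - ctr[3])^2)
    for (r0 in cases[[wl]]) {
      sel <- abs(r - r0) < h
      mc <- mean(f$values[sel])
      an <- mean(analytic_fluence(p, r = r[sel]))
      expect_lt(abs(mc / an - 1), 0.15,
                label = sprintf("MC/diffusion mismatch at %s nm, r = %g mm",
                                wl, r0))
    }
  }
})
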