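#' Optical properties of a homogeneous turbid medium
#'
#' Bundle the absorption coefficient, scattering coefficient, scattering
#' anisotropy and refractive index that drive photon transport at one
#' nominal wavelength.  Literature values for bulk soft tissue at the three
#' DiFC laser lines are available through [tissue_preset()].
#'
#' @param mu_a Absorption coefficient, mm^-1 (>= 0).
#' @param mu_s Scattering coefficient, mm^-1 (> 0).
#' @param g Scattering anisotropy (mean cosine of the single-scattering
#'   deflection angle), in (-1, 1).
#' @param n Refractive index of the medium (>= 1).
#' @param wavelength_nm Nominal wavelength label, nm (optional).
#'
#' @return An object of class `"optical_properties"`.
#' @seealso [tissue_preset()], [analytic_fluence()], [simulate_fluence()]
#' @export
#' @examples
#' optical_properties(mu_a = 0.002, mu_s = 7, g = 0.9, n = 1.37,
#'                    wavelength_nm = 780)
optical_properties <- function(mu_a, mu_s, g = 0.9, n = 1.37,
                               wavelength_nm = NA_real_) {
  stopifnot(is.numeric(mu_a), length(mu_a) == 1L,
            is.numeric(mu_s), length(mu_s) == 1L)
  if (mu_a < 0) stop("'mu_a' must be >= 0")
  if (mu_s <= 0) stop("'mu_s' must be > 0")
  if (abs(g) >= 1) stop("'g' must lie strictly between -1 and 1")
  if (n < 1) stop("'n' must be >= 1")
  structure(
    list(mu_a = mu_a, mu_s = mu_s, g = g, n = n,
         wavelength_nm = as.numeric(wavelength_nm)),
    class = "optical_properties")
}

#' Bulk-tissue optical property presets for the DiFC wavelengths
#'
#' Literature optical properties of bulk soft tissue at the blue-green
#' (488 nm), red (640 nm) and near-infrared (780 nm) DiFC laser lines.
#' All presets share g = 0.9 and n = 1.37.
#'
#' @param wavelength Preset name: `"488"`, `"640"` or `"780"` (numeric
#'   values are accepted).
#'
#' @return An [optical_properties()] object.
#' @export
#' @examples
#' tissue_preset("780")
tissue_preset <- function(wavelength = c("488", "640", "780")) {
  wavelength <- as.character(wavelength)[1L]
  presets <- list(
    "488" = c(mu_a = 0.05,  mu_s = 25),
    "640" = c(mu_a = 0.025, mu_s = 10),
    "780" = c(mu_a = 0.002, mu_s = 7))
  if (!wavelength %in% names(presets)) {
    stop("unknown wavelength preset '", wavelength,
         "'; available presets: ", paste(names(presets), collapse = ", "))
  }
  p <- presets[[wavelength]]
  optical_properties(mu_a = p[["mu_a"]], mu_s = p[["mu_s"]],
                     g = 0.9, n = 1.37,
                     wavelength_nm = as.numeric(wavelength))
}

#' @export
print.optical_properties <- function(x, ...) {
  cat("Optical properties",
      if (!is.na(x$wavelength_nm)) sprintf("(%g nm)", x$wavelength_nm),
      "\n")
  cat(sprintf("  mu_a = %g mm^-1, mu_s = %g mm^-1, g = %g, n = %g\n",
              x$mu_a, x$mu_s, x$g, x$n))
  cat(sprintf("  mu_s' = %g mm^-1, mu_eff = %g mm^-1\n",
              x$mu_s * (1 - x$g), mu_eff(x)))
  invisible(x)
}

#' Derived transport quantities
#'
#' `reduced_scattering()` returns mu_s' = mu_s (1 - g); `diffusion_constant()`
#' returns D = 1 / (3 (mu_a + mu_s')); `mu_eff()` returns
#' sqrt(3 mu_a (mu_a + mu_s')), the effective attenuation coefficient of
#' diffusion theory.
#'
#' @param props An [optical_properties()] object.
#' @return A numeric scalar (mm^-1 for `reduced_scattering()` and
#'   `mu_eff()`, mm for `diffusion_constant()`).
#' @export
reduced_scattering <- function(props) props$mu_s * (1 - props$g)

#' @rdname reduced_scattering
#' @export
diffusion_constant <- function(props) {
  1 / (3 * (props$mu_a + reduced_scattering(props)))
}

#' @rdname reduced_scattering
#' @export
mu_eff <- function(props) {
  sqrt(3 * props$mu_a * (props$mu_a + reduced_scattering(props)))
}

#' Voxel grid for Monte Carlo transport
#'
#' Defines the cubic (or rectangular) simulation domain.  The z axis points
#' into the tissue with z = 0 at the illuminated surface; x runs along the
#' source-detector axis and y along the vessel axis.  Voxel i spans
#' `[i * voxel_size, (i + 1) * voxel_size)` (0-based, half-open); positions
#' are in mm from the volume corner.
#'
#' @param extent Side length(s) in mm; a scalar or length-3 vector (x, y, z).
#'   Default 50 mm cube.
#' @param voxel_size Isotropic voxel edge, mm (default 0.25).
#'
#' @return An object of class `"voxel_volume"` with fields `extent`,
#'   `voxel_size` and `dims` (voxel counts).
#' @export
#' @examples
#' voxel_volume()            # 50 mm cube, 0.25-mm voxels (200^3)
#' voxel_volume(20, 0.25)    # smaller domain for quick runs
voxel_volume <- function(extent = 50, voxel_size = 0.25) {
  if (voxel_size <= 0) stop("'voxel_size' must be positive")
  extent <- rep_len(as.numeric(extent), 3L)
  dims <- extent / voxel_size
  if (any(abs(dims - round(dims)) > 1e-6)) {
    stop("'extent' must be divisible by 'voxel_size'")
  }
  structure(list(extent = extent, voxel_size = voxel_size,
                 dims = as.integer(round(dims))),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("Voxel volume: %g x %g x %g mm, %g-mm voxels (%d x %d x %d)\n",
              x$extent[1], x$extent[2], x$extent[3], x$voxel_size,
              x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Monte Carlo run configuration
#'
#' @param n_photons Number of photon packets to launch (default 1e8, the
#'   production budget; scale down for interactive use and tests).
#' @param time_gate_ns Maximum photon time of flight, ns (default 5).
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical tallies regardless of launch order.
#' @param roulette_threshold Packet weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survival Roulette survival probability (default 0.1).
#'
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(n_photons = 1e8, time_gate_ns = 5, seed = 1L,
                      roulette_threshold = 1e-4, roulette_survival = 0.1) {
  if (n_photons < 1) stop("'n_photons' must be >= 1")
  if (time_gate_ns <= 0) stop("'time_gate_ns' must be positive")
  if (roulette_survival <= 0 || roulette_survival > 1) {
    stop("'roulette_survival' must be in (0, 1]")
  }
  structure(list(n_photons = n_photons, time_gate_ns = time_gate_ns,
                 seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival),
            class = "mc_config")
}

#' Sample Henyey-Greenstein scattering deflections
#'
#' Draws the cosine of the polar deflection angle from the Henyey-Greenstein
#' phase function with anisotropy `g`, and a uniform azimuthal angle, from
#' supplied uniform variates (inverse-CDF sampling).  The mean of `cos_theta`
#' equals `g` analytically.
#'
#' @param g Anisotropy, strictly between -1 and 1.
#' @param u A two-column matrix (or length-2 vector) of uniforms in `[0, 1)`;
#'   column 1 drives the polar angle, column 2 the azimuth.
#'
#' @return A data frame with columns `cos_theta` and `phi` (radians).
#' @export
#' @examples
#' set.seed(1)
#' s <- hg_sample(0.9, cbind(runif(1e4), runif(1e4)))
#' mean(s$cos_theta)   # close to 0.9
hg_sample <- function(g, u) {
  if (abs(g) >= 1) stop("'g' must lie strictly between -1 and 1")
  u <- matrix(u, ncol = 2L)
  if (any(u < 0 | u >= 1)) stop("'u' components must lie in [0, 1)")
  if (abs(g) < 1e-12) {
    ct <- 2 * u[, 1L] - 1
  } else {
    f <- (1 - g^2) / (1 - g + 2 * g * u[, 1L])
    ct <- pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
  }
  data.frame(cos_theta = ct, phi = 2 * pi * u[, 2L])
}

#' Unpolarized Fresnel reflectance
#'
#' Reflectance of an unpolarized plane wave at a planar interface between
#' media of refractive index `n_in` (incidence side) and `n_out`.  Beyond the
#' critical angle the reflectance is 1 (total internal reflection).
#'
#' @param n_in,n_out Refractive indices (>= 1).
#' @param cos_incident Cosine of the incidence angle, in (0, 1]. Vectorized.
#'
#' @return Reflectance value(s) in `[0, 1]`.
#' @export
#' @examples
#' fresnel_reflectance(1.37, 1.0, 1)   # normal incidence, ~0.0244
fresnel_reflectance <- function(n_in, n_out, cos_incident) {
  if (n_in < 1 || n_out < 1) stop("refractive indices must be >= 1")
  if (any(cos_incident <= 0 | cos_incident > 1)) {
    stop("'cos_incident' must lie in (0, 1]")
  }
  if (n_in == n_out) return(rep_len(0, length(cos_incident)))
  ci <- cos_incident
  st2 <- (n_in / n_out)^2 * (1 - ci^2)
  r <- rep_len(1, length(ci))          # total internal reflection
  ok <- st2 < 1
  ct <- sqrt(pmax(0, 1 - st2[ok]))
  rs <- (n_in * ci[ok] - n_out * ct) / (n_in * ci[ok] + n_out * ct)
  rp <- (n_in * ct - n_out * ci[ok]) / (n_in * ct + n_out * ci[ok])
  r[ok] <- 0.5 * (rs^2 + rp^2)
  r
}

#' Monte Carlo fluence Green's function
#'
#' Launches weighted photon packets into a homogeneous voxelized medium and
#' tallies the fluence per launched photon in every voxel with the
#' path-length estimator.  Packets take scattering-sampled steps with
#' continuous absorption weighting, Henyey-Greenstein deflections, Fresnel
#' reflection/transmission at the z = 0 surface (refractive index mismatch
#' against air), termination at the five remaining faces, a time-of-flight
#' gate and Russian roulette.  Results are deterministic for a given seed:
#' per-photon random substreams are derived by counter.
#'
#' @param volume A [voxel_volume()].
#' @param props An [optical_properties()] object.
#' @param source Source position, mm; for the default pencil beam it must lie
#'   on the z = 0 face.
#' @param config An [mc_config()].
#' @param source_type `"pencil"` (collimated beam along `direction`) or
#'   `"isotropic"` (point source, any interior position).
#' @param direction Launch direction for a pencil beam (must point into the
#'   medium); default normal incidence.
#' @param boundaries `"cube"` (default: Fresnel surface at z = 0, absorbing
#'   side/bottom faces) or `"none"` (infinite medium: photons propagate
#'   beyond the tallied grid unimpeded).
#'
#' @return An object of class `"fluence_field"`: a list with `values` (3D
#'   array, fluence per launched photon, mm^-2), `source_position`, the
#'   geometry/configuration metadata and packet-weight tallies
#'   (`absorbed_weight`, `escaped_weight`, `gated_weight`, `roulette_loss`,
#'   `roulette_gain`, all per launched photon).
#' @seealso [weight_balance()], [analytic_fluence()], [born_sensitivity()]
#' @export
#' @examples
#' vol <- voxel_volume(10, 0.5)
#' f <- simulate_fluence(vol, tissue_preset("780"),
#'                       source = c(5, 5, 0),
#'                       config = mc_config(n_photons = 2e4, seed = 7))
#' weight_balance(f)   # ~1 (all launched weight accounted for)
simulate_fluence <- function(volume, props, source,
                             config = mc_config(),
                             source_type = c("pencil", "isotropic"),
                             direction = c(0, 0, 1),
                             boundaries = c("cube", "none")) {
  source_type <- match.arg(source_type)
  boundaries <- match.arg(boundaries)
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(props, "optical_properties"),
            inherits(config, "mc_config"))
  source <- as.numeric(source)
  if (length(source) != 3L) stop("'source' must be a length-3 position")
  if (source_type == "pencil") {
    if (abs(source[3]) > 1e-9) {
      stop("a pencil-beam source must lie on the z = 0 face")
    }
    direction <- direction / sqrt(sum(direction^2))
    if (direction[3] <= 0) stop("launch direction must point into the medium")
  }
  inside_face <- source[1] >= 0 & source[1] <= volume$extent[1] &
    source[2] >= 0 & source[2] <= volume$extent[2]
  if (!inside_face) stop("source position lies outside the volume face")

  res <- .mc_fluence_cpp(volume$dims, volume$voxel_size,
                         props$mu_a, props$mu_s, props$g, props$n,
                         source, as.numeric(direction), source_type,
                         config$n_photons, config$time_gate_ns,
                         as.double(config$seed),
                         config$roulette_threshold, config$roulette_survival,
                         boundaries == "cube")
  values <- array(res$fluence, dim = volume$dims)
  structure(
    list(values = values, volume = volume, props = props,
         source_position = source, source_type = source_type,
         boundaries = boundaries, config = config,
         absorbed_weight = res$absorbed_weight,
         escaped_weight = res$escaped_weight,
         gated_weight = res$gated_weight,
         roulette_loss = res$roulette_loss,
         roulette_gain = res$roulette_gain),
    class = "fluence_field")
}

#' Packet-weight balance of a Monte Carlo run
#'
#' Absorbed + escaped + in-flight-at-gate weight, net of the Russian-roulette
#' adjustment, per launched photon.  Equals 1 up to floating-point rounding
#' for every run (conservation of launched weight).
#'
#' @param field A [simulate_fluence()] result.
#' @return A numeric scalar (should be 1 within 1e-6 relative).
#' @export
weight_balance <- function(field) {
  stopifnot(inherits(field, "fluence_field"))
  field$absorbed_weight + field$escaped_weight + field$gated_weight +
    field$roulette_loss - field$roulette_gain
}

#' @export
print.fluence_field <- function(x, ...) {
  cat(sprintf("Fluence field (%s source at %.2f, %.2f, %.2f mm; %s)\n",
              x$source_type, x$source_position[1], x$source_position[2],
              x$source_position[3],
              if (x$boundaries == "cube") "bounded cube" else "infinite medium"))
  cat(sprintf("  %g photons, seed %d, gate %g ns\n",
              x$config$n_photons, x$config$seed, x$config$time_gate_ns))
  cat(sprintf("  weight: absorbed %.4f, escaped %.4f, gated %.4f (balance %.8f)\n",
              x$absorbed_weight, x$escaped_weight, x$gated_weight,
              weight_balance(x)))
  invisible(x)
}

#' Diffusion-theory fluence (closed form)
#'
#' Continuous-wave diffusion-approximation fluence of a unit isotropic point
#' source, used as an independent oracle for the Monte Carlo transport.  The
#' infinite-medium solution is `exp(-mu_eff r) / (4 pi D r)`.  The
#' semi-infinite variant uses the extrapolated-boundary image-source
#' construction for a pencil beam incident at the origin: the real isotropic
#' source sits at depth `z0 = 1/(mu_a + mu_s')`, the negative image at
#' `-(z0 + 2 zb)` with `zb = 2 A D`, and the fluence is evaluated at
#' cylindrical radius `rho` and depth `z`.
#'
#' @param props An [optical_properties()] object.
#' @param r Source-point distance, mm (infinite geometry; must be > 0).
#' @param geometry `"infinite"` or `"semi-infinite"`.
#' @param rho,z Cylindrical radius and depth, mm (semi-infinite geometry).
#'
#' @return Fluence per unit source strength, mm^-2. Vectorized over
#'   `r` (or `rho`/`z`).
#' @export
#' @examples
#' analytic_fluence(tissue_preset("780"), r = 5)
analytic_fluence <- function(props, r = NULL,
                             geometry = c("infinite", "semi-infinite"),
                             rho = NULL, z = NULL) {
  geometry <- match.arg(geometry)
  D <- diffusion_constant(props)
  mueff <- mu_eff(props)
  if (geometry == "infinite") {
    if (is.null(r)) stop("'r' is required for the infinite geometry")
    if (any(r <= 0)) stop("'r' must be positive (point-source singularity at r = 0)")
    return(exp(-mueff * r) / (4 * pi * D * r))
  }
  if (is.null(rho) || is.null(z)) {
    stop("'rho' and 'z' are required for the semi-infinite geometry")
  }
  z0 <- 1 / (props$mu_a + reduced_scattering(props))
  zb <- 2 * boundary_A(props$n) * D
  r1 <- sqrt(rho^2 + (z - z0)^2)
  r2 <- sqrt(rho^2 + (z + z0 + 2 * zb)^2)
  if (any(r1 == 0)) stop("evaluation point coincides with the source singularity")
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * D)
}

# internal-reflection boundary coefficient A = (1 + R_eff) / (1 - R_eff),
# Groenhuis-style polynomial fit in the refractive index mismatch
boundary_A <- function(n) {
  r_eff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + r_eff) / (1 - r_eff)
}

#' Extrapolated-boundary depth of the semi-infinite diffusion model
#'
#' Returns `zb = 2 A D`: the semi-infinite fluence of [analytic_fluence()]
#' vanishes on the plane `z = -zb` by construction.
#'
#' @param props An [optical_properties()] object.
#' @return Depth in mm (positive; the plane lies outside the medium).
#' @export
extrapolation_depth <- function(props) {
  2 * boundary_A(props$n) * diffusion_constant(props)
}
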