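#' Probe positions on the tissue surface for a given separation
#'
#' Source and detector are placed on the z = 0 face, centered on the face and
#' offset by half the source-detector separation (SDS) along x.
#'
#' @param volume A [voxel_volume()].
#' @param sds Source-detector separation, mm (>= 0, within the face).
#' @return A list with `source` and `detector` positions (mm).
#' @export
probe_positions <- function(volume, sds) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (sds < 0 || sds > volume$extent[1]) {
    stop("'sds' must lie within the volume face")
  }
  cx <- volume$extent[1] / 2
  cy <- volume$extent[2] / 2
  list(source = c(cx - sds / 2, cy, 0),
       detector = c(cx + sds / 2, cy, 0))
}

#' Mirror a fluence field across the vertical mid-plane of the volume
#'
#' In a homogeneous medium whose grid is symmetric about the plane
#' `x = extent/2`, the fluence of a normally incident pencil beam at
#' `(cx + d, cy, 0)` is the x-mirror of the fluence from `(cx - d, cy, 0)`.
#' [sds_sweep()] uses this to obtain the detector-launched adjoint Green's
#' function from the source run without a second simulation.
#'
#' @param field A [simulate_fluence()] result.
#' @return A `"fluence_field"` with values flipped along x and the source
#'   position mirrored.
#' @export
mirror_field_x <- function(field) {
  stopifnot(inherits(field, "fluence_field"))
  nx <- dim(field$values)[1L]
  field$values <- field$values[nx:1, , , drop = FALSE]
  field$source_position[1] <-
    field$volume$extent[1] - field$source_position[1]
  field
}

#' Born-approximation fluorescence sensitivity matrix (Jacobian)
#'
#' Assembles the continuous-wave fluorescence sensitivity of one
#' source-detector pair from two Green's functions: the excitation fluence
#' launched from the source, and the emission Green's function obtained by
#' the adjoint trick -- a forward run launched from the detector position,
#' valid by reciprocity.  Each voxel's sensitivity is the product of the two
#' fluences times the voxel volume (single-voxel quadrature of the Born
#' integral).
#'
#' @param g_ex Excitation [simulate_fluence()] field, launched at the source.
#' @param g_em_adjoint Emission field launched at the detector position.
#'
#' @return An object of class `"sensitivity_map"`: list with `W` (3D
#'   non-negative array), `volume`, `props`, `source_position`, `detector_position`,
#'   `sds`, `wavelength_nm`.
#' @export
#' @examples
#' vol <- voxel_volume(10, 0.5)
#' pr <- probe_positions(vol, 2)
#' cfg <- mc_config(n_photons = 2e4, seed = 3)
#' gs <- simulate_fluence(vol, tissue_preset("780"), pr$source, cfg)
#' gd <- simulate_fluence(vol, tissue_preset("780"), pr$detector, cfg)
#' W <- born_sensitivity(gs, gd)
born_sensitivity <- function(g_ex, g_em_adjoint) {
  stopifnot(inherits(g_ex, "fluence_field"),
            inherits(g_em_adjoint, "fluence_field"))
  if (!identical(dim(g_ex$values), dim(g_em_adjoint$values)) ||
      g_ex$volume$voxel_size != g_em_adjoint$volume$voxel_size) {
    stop("excitation and emission fields are on incompatible grids")
  }
  dV <- g_ex$volume$voxel_size^3
  rs <- g_ex$source_position
  rd <- g_em_adjoint$source_position
  surface_pencils <- g_ex$source_type == "pencil" &&
    g_em_adjoint$source_type == "pencil" &&
    abs(rs[3]) < 1e-9 && abs(rd[3]) < 1e-9
  structure(
    list(W = g_ex$values * g_em_adjoint$values * dV,
         volume = g_ex$volume, props = g_ex$props,
         source_position = rs, detector_position = rd,
         sds = sqrt(sum((rs - rd)^2)),
         wavelength_nm = g_ex$props$wavelength_nm,
         radial_ex = if (surface_pencils) radial_green(g_ex),
         radial_em = if (surface_pencils) radial_green(g_em_adjoint)),
    class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("Born sensitivity map: SDS %.2f mm%s\n", x$sds,
              if (!is.na(x$wavelength_nm))
                sprintf(" at %g nm", x$wavelength_nm) else ""))
  cat(sprintf("  grid %d x %d x %d (%g-mm voxels); sum(W) = %.4g\n",
              dim(x$W)[1], dim(x$W)[2], dim(x$W)[3],
              x$volume$voxel_size, sum(x$W)))
  invisible(x)
}

# indices of the voxel column(s) containing surface coordinate `pos` along
# one axis; a coordinate on a voxel boundary selects the two adjacent
# columns (averaged downstream to avoid half-voxel bias)
.columns_at <- function(pos, voxel_size, n) {
  k <- pos / voxel_size
  if (abs(k - round(k)) < 1e-9) {           # on a boundary
    idx <- c(round(k), round(k) + 1L)
  } else {
    idx <- floor(k) + 1L                    # 1-based voxel index
    return(if (idx >= 1L && idx <= n) as.integer(idx) else
             stop("position off-grid"))
  }
  idx <- idx[idx >= 1L & idx <= n]
  if (!length(idx)) stop("position off-grid")
  as.integer(idx)
}

# average of the vertical voxel columns through surface point (x, y)
.midline_column <- function(map, x, y) {
  h <- map$volume$voxel_size
  ix <- .columns_at(x, h, dim(map$W)[1L])
  iy <- .columns_at(y, h, dim(map$W)[2L])
  cols <- map$W[ix, iy, , drop = FALSE]
  apply(cols, 3L, mean)
}

#' Midline depth profile of a sensitivity map
#'
#' Extracts the sensitivity along the vertical voxel column through the
#' surface midpoint between source and detector, the standard summary of how
#' deep a probe geometry "sees".  When the midpoint falls on a voxel
#' boundary the adjacent columns are averaged.
#'
#' @param map A [born_sensitivity()] map whose source and detector lie on
#'   the z = 0 face.
#' @param max_depth Deepest voxel-center depth to report, mm (default 5).
#' @param estimator `"voxel"` (default: read the voxel column through the
#'   probe midpoint, averaging adjacent columns when the midpoint falls on
#'   a voxel boundary) or `"radial"` (ring-averaged Green's functions, see
#'   [radial_green()]; much lower Monte Carlo variance, identical
#'   expectation up to the rotational symmetry of the homogeneous medium).
#'
#' @return A data frame of class `"depth_profile"` with columns `depth_mm`
#'   (voxel centers, strictly increasing) and `value`, plus attributes
#'   `normalization` (`"raw"`), `sds_mm` and `wavelength_nm`.
#' @export
midline_depth_profile <- function(map, max_depth = 5,
                                  estimator = c("voxel", "radial")) {
  stopifnot(inherits(map, "sensitivity_map"))
  estimator <- match.arg(estimator)
  if (abs(map$source_position[3]) > 1e-9 ||
      abs(map$detector_position[3]) > 1e-9) {
    stop("source and detector must lie on the z = 0 face")
  }
  mid <- (map$source_position + map$detector_position) / 2
  col <- if (estimator == "radial") {
    .radial_midline(map)
  } else {
    .midline_column(map, mid[1], mid[2])
  }
  h <- map$volume$voxel_size
  depths <- (seq_along(col) - 0.5) * h
  keep <- depths <= max_depth + 1e-9
  structure(
    data.frame(depth_mm = depths[keep], value = col[keep]),
    normalization = "raw",
    sds_mm = map$sds, wavelength_nm = map$wavelength_nm,
    class = c("depth_profile", "data.frame"))
}

#' Depth of maximum sensitivity
#'
#' Voxel-center depth at which a midline profile attains its maximum; ties
#' are broken toward the shallowest depth.
#'
#' @param profile A [midline_depth_profile()] result.
#' @return Depth in mm.
#' @export
depth_of_max_sensitivity <- function(profile) {
  if (!nrow(profile)) stop("empty profile")
  if (all(profile$value == 0)) {
    stop("all-zero profile: maximum depth undefined")
  }
  profile$depth_mm[which.max(profile$value)]
}

#' Normalize a collection of depth profiles to their global maximum
#'
#' Divides every profile by the single maximum over the whole collection,
#' so that exactly one value equals 1 afterwards.  This is the normalization
#' used when comparing depth profiles across SDS and wavelength on a common
#' scale.
#'
#' @param profiles A list of raw [midline_depth_profile()] objects.
#' @return The same list with values scaled and `normalization` set to
#'   `"normalized-to-global-max"`.
#' @export
normalize_profiles <- function(profiles) {
  if (!length(profiles)) stop("empty profile collection")
  if (!all(vapply(profiles, function(p)
    attr(p, "normalization") == "raw", logical(1L)))) {
    stop("profiles must be raw (not already normalized)")
  }
  gmax <- max(vapply(profiles, function(p) max(p$value), numeric(1L)))
  if (gmax == 0) stop("all-zero profile collection: maximum undefined")
  lapply(profiles, function(p) {
    p$value <- p$value / gmax
    attr(p, "normalization") <- "normalized-to-global-max"
    p
  })
}

#' @export
plot.depth_profile <- function(x, ...) {
  graphics::plot(x$depth_mm, x$value, type = "l",
                 xlab = "depth (mm)",
                 ylab = sprintf("sensitivity (%s)", attr(x, "normalization")),
                 ...)
  invisible(x)
}

#' Sweep of Born sensitivity maps over source-detector separations
#'
#' Runs the excitation Green's function for every SDS in the list and forms
#' the adjoint emission field either by a second simulation launched from
#' the detector or -- by default -- by mirroring the source field across the
#' volume mid-plane, exact for this symmetric homogeneous geometry (see
#' [mirror_field_x()]).  The per-SDS seeds are offset from `config$seed` so
#' maps are independent but fully reproducible.
#'
#' @param props An [optical_properties()] object (one wavelength).
#' @param sds_list Separations in mm (default the production grid
#'   `c(0.3, 1, 2, 3, 5, 6, 12)`).
#' @param volume A [voxel_volume()].
#' @param config An [mc_config()].
#' @param use_symmetry Mirror the source run for the detector field
#'   (default `TRUE`); set `FALSE` for two independent simulations.
#'
#' @return A named list of [born_sensitivity()] maps keyed by SDS.
#' @export
sds_sweep <- function(props, sds_list = c(0.3, 1, 2, 3, 5, 6, 12),
                      volume = voxel_volume(), config = mc_config(),
                      use_symmetry = TRUE) {
  if (!length(sds_list)) stop("'sds_list' must be non-empty")
  maps <- lapply(seq_along(sds_list), function(i) {
    sds <- sds_list[i]
    pr <- probe_positions(volume, sds)
    cfg <- config
    cfg$seed <- config$seed + (i - 1L) * 2L
    g_ex <- simulate_fluence(volume, props, pr$source, cfg)
    g_em <- if (use_symmetry) {
      mirror_field_x(g_ex)
    } else {
      cfg2 <- cfg
      cfg2$seed <- cfg$seed + 1L
      simulate_fluence(volume, props, pr$detector, cfg2)
    }
    born_sensitivity(g_ex, g_em)
  })
  names(maps) <- as.character(sds_list)
  maps
}
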