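#' Azimuthally averaged (radial) Green's function
#'
#' For a normally incident pencil beam on a homogeneous medium the fluence
#' is rotationally symmetric about the beam axis, so all voxels at the same
#' lateral distance rho and depth z estimate the same value.  Averaging
#' over those rings reduces the Monte Carlo variance of point reads by one
#' to two orders of magnitude; the residual symmetry breaking by the distant
#' cube side walls is negligible at the radii of interest.
#'
#' @param field A [simulate_fluence()] result (pencil beam normal to the
#'   surface).
#' @param rho_max Largest lateral distance retained, mm (default half the
#'   x extent).
#' @return A list of class `"radial_green"` with `rho` (count-weighted mean
#'   ring radius per bin, mm), `z` (voxel-center depths, mm) and `g`
#'   (matrix `length(rho)` x `length(z)` of ring-averaged fluence).
#' @export
radial_green <- function(field, rho_max = NULL) {
  stopifnot(inherits(field, "fluence_field"))
  h <- field$volume$voxel_size
  d <- dim(field$values)
  if (is.null(rho_max)) rho_max <- field$volume$extent[1] / 2
  xc <- ((seq_len(d[1]) - 0.5) * h) - field$source_position[1]
  yc <- ((seq_len(d[2]) - 0.5) * h) - field$source_position[2]
  rho <- sqrt(outer(xc^2, yc^2, `+`))
  bin <- as.integer(floor(rho / h)) + 1L
  keep <- rho <= rho_max
  nb <- max(bin[keep])
  counts <- tabulate(bin[keep], nb)
  rho_mean <- as.numeric(rowsum(rho[keep], bin[keep], reorder = TRUE)) / counts
  flat <- matrix(field$values, d[1] * d[2], d[3])
  g <- rowsum(flat[keep, , drop = FALSE], bin[keep], reorder = TRUE) / counts
  structure(list(rho = rho_mean, z = (seq_len(d[3]) - 0.5) * h, g = g),
            class = "radial_green")
}

# interpolate a radial Green's function at lateral distance rho for every
# depth; linear in log(g) where positive, linear otherwise
.radial_at <- function(rg, rho) {
  n <- length(rg$rho)
  if (rho <= rg$rho[1]) {
    i <- 1L
  } else if (rho >= rg$rho[n]) {
    i <- n - 1L
  } else {
    i <- findInterval(rho, rg$rho)
  }
  f <- (rho - rg$rho[i]) / (rg$rho[i + 1L] - rg$rho[i])
  g1 <- rg$g[i, ]
  g2 <- rg$g[i + 1L, ]
  out <- ifelse(g1 > 0 & g2 > 0,
                exp((1 - f) * log(pmax(g1, 1e-300)) +
                      f * log(pmax(g2, 1e-300))),
                (1 - f) * g1 + f * g2)
  as.numeric(out)
}

# ring-averaged midline sensitivity per depth layer for a map that carries
# radial profiles of its two Green's functions
.radial_midline <- function(map) {
  rex <- map$radial_ex
  rem <- map$radial_em
  if (is.null(rex) || is.null(rem)) {
    stop("map does not carry radial Green's function profiles")
  }
  dV <- map$volume$voxel_size^3
  half <- map$sds / 2
  .radial_at(rex, half) * .radial_at(rem, half) * dV
}
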