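#' Photon records scored at a plane
#'
#' A table of photons crossing a named axial plane: in-line position `y`
#' (mm), plane `z` (cm), unit direction components `u` (in-line) and `v`
#' (axial, must be positive: photons travel downstream), energy (MeV) and
#' statistical weight.
#'
#' @param y,z,u,v,energy,weight Numeric vectors (recycled to a common
#'   length).
#' @param source Optional character label (e.g. `"primary"`).
#' @return A `data.frame` of class `photon_records`.
#' @export
photon_records <- function(y, z, u, v, energy, weight = 1, source = NA) {
  df <- data.frame(y = y, z = z, u = u, v = v, energy = energy,
                   weight = weight, source = source)
  norm <- sqrt(df$u^2 + df$v^2)
  if (any(abs(norm - 1) > 1e-6))
    stop("(u, v) must be unit direction components", call. = FALSE)
  if (any(df$energy <= 0)) stop("energies must be positive", call. = FALSE)
  if (any(df$weight <= 0)) stop("weights must be positive", call. = FALSE)
  class(df) <- c("photon_records", "data.frame")
  df
}

#' In-line trajectory intercept at an axial plane
#'
#' Straight-line continuation of each record to the plane `z_cm`.
#'
#' @param records A [photon_records()] table.
#' @param z_cm Target plane (cm).
#' @return Intercept positions (mm).
#' @export
trajectory_intercept <- function(records, z_cm) {
  records$y + records$u / records$v * (z_cm - records$z) * CM2MM
}

#' Back-project photon records to an upstream plane
#'
#' Moves every record along its own straight-line trajectory to `z_plane`;
#' directions, energies and weights are unchanged.  Records with a
#' non-positive axial direction component cannot be projected and are
#' dropped with a reported count.
#'
#' @param records A [photon_records()] table.
#' @param z_plane Destination plane (cm), upstream of the records.
#' @return The projected [photon_records()].
#' @export
backproject <- function(records, z_plane) {
  if (nrow(records) == 0) return(records)
  bad <- records$v <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) with non-positive axial direction rejected")
    records <- records[!bad, , drop = FALSE]
  }
  if (any(records$z < z_plane))
    stop("all records must lie downstream of z_plane", call. = FALSE)
  records$y <- trajectory_intercept(records, z_plane)
  records$z <- rep(z_plane, nrow(records))
  records
}

#' Primary-source photon elimination
#'
#' Keeps only photons whose straight-line trajectories intersect the
#' isocenter plane within `window_mm` of the axis, the inclusion criterion
#' used when extracting the primary (target) source for a small field.
#' Filtering uses trajectories, not stored positions, so it commutes with
#' [backproject()].
#'
#' @param records A [photon_records()] table.
#' @param geom A [beam_geometry()].
#' @param window_mm Half-width of the in-line acceptance window at the
#'   isocenter plane (mm); default 10.
#' @return Filtered [photon_records()].
#' @export
primary_elimination <- function(records, geom = beam_geometry(),
                                window_mm = 10) {
  if (nrow(records) == 0) return(records)
  keep <- abs(trajectory_intercept(records, geom$z_isocenter)) <= window_mm
  records[keep, , drop = FALSE]
}

#' Secondary-source photon elimination
#'
#' Keeps only photons whose trajectories cross the secondary-source plane
#' (distal side of the flattening filter) within `window_mm` of the axis
#' (default +-7 cm).
#'
#' @inheritParams primary_elimination
#' @param window_mm Half-width of the acceptance window at the secondary
#'   plane (mm); default 70.
#' @return Filtered [photon_records()].
#' @export
secondary_elimination <- function(records, geom = beam_geometry(),
                                  window_mm = 70) {
  if (nrow(records) == 0) return(records)
  keep <- abs(trajectory_intercept(records, geom$z_filter_distal)) <= window_mm
  records[keep, , drop = FALSE]
}

#' Weighted maximum-likelihood Gaussian FWHM
#'
#' Fits a Gaussian to weighted in-line positions by maximum likelihood and
#' returns its full width at half maximum, `2 sqrt(2 ln 2) sigma`.
#'
#' @param positions Numeric positions (mm).
#' @param weights Optional statistical weights.
#' @return FWHM in mm; 0 (with a warning) for degenerate all-equal input.
#' @examples
#' fit_gaussian_fwhm(stats::rnorm(1e4))   # ~2.355
#' @export
fit_gaussian_fwhm <- function(positions, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(positions))
  stopifnot(length(weights) == length(positions))
  mu <- sum(weights * positions) / sum(weights)
  sigma2 <- sum(weights * (positions - mu)^2) / sum(weights)
  if (sigma2 == 0) {
    warning("degenerate position sample: FWHM is 0")
    return(0)
  }
  2 * sqrt(2 * log(2)) * sqrt(sigma2)
}

#' Source contribution weights from photon counts
#'
#' Relative weight of each virtual source as the ratio of its photon count
#' at the isocenter plane to the total.
#'
#' @param n_primary_at_iso,n_secondary_at_iso Photon counts (or summed
#'   statistical weights) at the isocenter plane.
#' @return Named numeric `c(w_p, w_s)` summing to 1.
#' @export
derive_weights <- function(n_primary_at_iso, n_secondary_at_iso) {
  if (n_primary_at_iso < 0 || n_secondary_at_iso < 0)
    stop("counts must be >= 0", call. = FALSE)
  total <- n_primary_at_iso + n_secondary_at_iso
  if (total == 0) stop("at least one count must be positive", call. = FALSE)
  c(w_p = n_primary_at_iso / total, w_s = n_secondary_at_iso / total)
}

#' Virtual photon source
#'
#' Spatial, spectral and angular description of one virtual source.
#'
#' The angular model gives the emission density over the in-line intercept
#' at the isocenter plane for a photon emitted at `y_source`:
#' * `"focal"`: Gaussian about the mean intercept, normalized over the
#'   source's acceptance window.  The mean intercept is the divergent
#'   projection of the emission point from `divergence_origin_z` (the
#'   focal spot); with `divergence_origin_z = NULL` the mean direction is
#'   parallel to the beam axis.  The Gaussian width is
#'   `angular_spread` (mrad) times the source-isocenter distance, so the
#'   angular distribution a point "sees" varies across the beam.
#' * `"uniform"`: constant density `1/(2 * window)` over the acceptance
#'   window.
#'
#' @param z_source Axial source position (cm).
#' @param spatial List describing the spatial emission density: one of
#'   `list(type = "point")`, `list(type = "gaussian", fwhm = <mm>)`,
#'   `list(type = "disc", radius = <mm>)` (a uniform strip of half-width
#'   `radius` in this 1D model).
#' @param spectrum A [photon_spectrum()].
#' @param angular List: `type` (`"focal"` or `"uniform"`), `spread`
#'   (mrad), `window` (acceptance half-width at isocenter, mm) and
#'   optionally `divergence_origin_z` (cm).
#' @param rel_weight Fraction of the total isocenter-plane photons carried
#'   by this source.
#' @return Object of class `virtual_source`.
#' @examples
#' primary_source()
#' @export
virtual_source <- function(z_source, spatial, spectrum, angular,
                           rel_weight = 1) {
  stopifnot(spatial$type %in% c("point", "gaussian", "disc"))
  if (spatial$type == "gaussian" && spatial$fwhm < 0)
    stop("gaussian FWHM must be >= 0", call. = FALSE)
  if (spatial$type == "disc" && spatial$radius < 0)
    stop("disc radius must be >= 0", call. = FALSE)
  stopifnot(angular$type %in% c("focal", "uniform"))
  if (rel_weight < 0 || rel_weight > 1)
    stop("rel_weight must be in [0, 1]", call. = FALSE)
  if (abs(sum(spectrum$probs) - 1) > 1e-9)
    stop("spectrum probabilities must sum to 1", call. = FALSE)
  structure(list(z_source = z_source, spatial = spatial, spectrum = spectrum,
                 angular = angular, rel_weight = rel_weight),
            class = "virtual_source")
}

#' @export
print.virtual_source <- function(x, ...) {
  sp <- switch(x$spatial$type,
               point = "point",
               gaussian = sprintf("Gaussian FWHM %.3g mm", x$spatial$fwhm),
               disc = sprintf("uniform disc radius %.3g mm", x$spatial$radius))
  cat(sprintf(
    "Virtual source at Z = %.3g cm: %s, %s MeV mean, %s angular, weight %.3g\n",
    x$z_source, sp, format(x$spectrum$mean), x$angular$type, x$rel_weight))
  invisible(x)
}

#' Default primary (target) virtual source
#'
#' Gaussian focal spot of FWHM 1.05 mm at the distal side of the target,
#' mean photon energy 1.6 MeV.
#'
#' @param fwhm Spatial FWHM (mm).
#' @param mean_energy Mean photon energy (MeV).
#' @param energy_mode `"mono"` or `"poly"`.
#' @param angular_type `"focal"` or `"uniform"`.
#' @param angular_spread Gaussian angular spread (mrad).
#' @param rel_weight Source weight.
#' @param geom A [beam_geometry()].
#' @return A [virtual_source()].
#' @export
primary_source <- function(fwhm = 1.05, mean_energy = 1.6,
                           energy_mode = "mono", angular_type = "focal",
                           angular_spread = 23, rel_weight = 0.95,
                           geom = beam_geometry()) {
  virtual_source(
    z_source = geom$z_target_distal,
    spatial = list(type = "gaussian", fwhm = fwhm),
    spectrum = photon_spectrum(mean_energy, energy_mode),
    angular = list(type = angular_type, spread = angular_spread, window = 10,
                   divergence_origin_z = NULL),
    rel_weight = rel_weight)
}

#' Default secondary (head-scatter) virtual source
#'
#' Broad Gaussian source at the distal plane of the flattening filter,
#' mean photon energy 0.7 MeV, divergent from the focal spot.
#'
#' @param fwhm Spatial FWHM (mm).
#' @param mean_energy Mean photon energy (MeV).
#' @param energy_mode `"mono"` or `"poly"`.
#' @param angular_type `"focal"` or `"uniform"`.
#' @param angular_spread Gaussian angular spread (mrad).
#' @param rel_weight Source weight.
#' @param geom A [beam_geometry()].
#' @return A [virtual_source()].
#' @export
secondary_source <- function(fwhm = 30, mean_energy = 0.7,
                             energy_mode = "mono", angular_type = "focal",
                             angular_spread = 100, rel_weight = 0.05,
                             geom = beam_geometry()) {
  virtual_source(
    z_source = geom$z_filter_distal,
    spatial = list(type = "gaussian", fwhm = fwhm),
    spectrum = photon_spectrum(mean_energy, energy_mode),
    angular = list(type = angular_type, spread = angular_spread, window = 70,
                   divergence_origin_z = 0),
    rel_weight = rel_weight)
}

spatial_density <- function(source, y) {
  sp <- source$spatial
  switch(sp$type,
         point = stop("point sources carry a Dirac spatial density; ",
                      "handled by the integrator", call. = FALSE),
         gaussian = {
           sigma <- sp$fwhm / (2 * sqrt(2 * log(2)))
           if (sigma == 0) stop("degenerate gaussian source", call. = FALSE)
           stats::dnorm(y, 0, sigma)
         },
         disc = ifelse(abs(y) <= sp$radius, 1 / (2 * sp$radius), 0))
}

## support half-width of the spatial density (mm); point sources have 0
spatial_support <- function(source, cut_sigmas = 5) {
  sp <- source$spatial
  switch(sp$type,
         point = 0,
         gaussian = cut_sigmas * sp$fwhm / (2 * sqrt(2 * log(2))),
         disc = sp$radius)
}

angular_density <- function(source, y_source, y_iso, geom = beam_geometry()) {
  a <- source$angular
  w <- a$window
  if (a$type == "uniform") return(rep(1 / (2 * w), length(y_source)))
  dz <- (geom$z_isocenter - source$z_source) * CM2MM
  sigma_y <- a$spread / 1000 * dz
  zf <- a$divergence_origin_z
  y0 <- if (is.null(zf)) y_source
        else y_source * (geom$z_isocenter - zf) / (source$z_source - zf)
  mass <- stats::pnorm((w - y0) / sigma_y) - stats::pnorm((-w - y0) / sigma_y)
  stats::dnorm(y_iso, y0, sigma_y) / mass
}

#' Emission density of a virtual source toward an isocenter point
#'
#' Product of the spatial emission density at `y_source` and the angular
#' density of the direction `(y_source -> y_iso)`, both per mm.  For a
#' point source the spatial factor is a Dirac mass at `y_source = 0`
#' (collapsed analytically by the fluence integrator); here the angular
#' factor alone is returned at `y_source = 0` and 0 elsewhere.
#'
#' @param source A [virtual_source()].
#' @param y_source Emission position(s) on the source plane (mm).
#' @param y_iso Target position on the isocenter plane (mm).
#' @param geom A [beam_geometry()].
#' @return Emission density (per mm per mm).
#' @export
emit <- function(source, y_source, y_iso, geom = beam_geometry()) {
  ang <- angular_density(source, y_source, y_iso, geom)
  if (source$spatial$type == "point")
    return(ifelse(y_source == 0, ang, 0))
  spatial_density(source, y_source) * ang
}
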