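#' Synthetic phase-space generator configuration
#'
#' Parameters of the synthetic photon records scored at the plane below the
#' flattening filter.  Defaults reproduce the statistical structure the
#' source-extraction procedure assumes: a Gaussian focal spot of FWHM
#' 1.05 mm at the distal side of the target emitting forward-directed
#' primary photons with mean energy 1.6 MeV, plus a broad secondary
#' (head-scatter) component at the scoring plane with mean energy 0.7 MeV.
#'
#' @param n_photons Number of records to generate.
#' @param seed Integer seed; the generator is stream-stable for a fixed
#'   seed.
#' @param focal_fwhm Focal-spot FWHM (mm).
#' @param focal_z Focal-spot plane (cm).
#' @param scoring_z Scoring plane (cm).
#' @param primary_fraction Fraction of records drawn from the primary
#'   component.
#' @param primary_mean_energy,secondary_mean_energy Mean energies (MeV).
#' @param secondary_spatial_fwhm Secondary spatial FWHM at the scoring
#'   plane (mm).
#' @param angular_spread Gaussian angular noise added to the primary
#'   aiming directions (mrad).
#' @param aim_window Half-width of the isocenter window the primary
#'   photons are aimed into (mm).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_photons = 1e5, seed = 1, focal_fwhm = 1.05,
                             focal_z = 1.1, scoring_z = 15.9,
                             primary_fraction = 0.95,
                             primary_mean_energy = 1.6,
                             secondary_mean_energy = 0.7,
                             secondary_spatial_fwhm = 30,
                             angular_spread = 23, aim_window = 12) {
  stopifnot(n_photons > 0, primary_fraction >= 0, primary_fraction <= 1,
            focal_fwhm >= 0, scoring_z > focal_z)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate synthetic photon records at the scoring plane
#'
#' Samples photon records with the structure assumed by the virtual-source
#' extraction: primary records originate at a Gaussian focal spot and are
#' aimed toward a point drawn uniformly in a window at the isocenter plane
#' somewhat wider than the +-10 mm primary elimination window, plus
#' Gaussian angular noise (so the elimination filter has a non-trivial
#' accept/reject load); secondary records originate across the scoring
#' plane with divergent directions and broader angular noise.  Energies
#' are drawn from bremsstrahlung-like [photon_spectrum()] tables with the
#' configured means.  Sampling order is fixed (labels, then positions,
#' aims, noise, energies), so streams are reproducible for a given seed.
#'
#' @param config A [generator_config()].
#' @return A [photon_records()] table at `config$scoring_z` with a
#'   `source` label column.
#' @examples
#' ps <- generate_phasespace(generator_config(n_photons = 1000))
#' table(ps$source)
#' @export
generate_phasespace <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_photons
  is_primary <- stats::runif(n) < config$primary_fraction
  np <- sum(is_primary); ns <- n - np
  sigma_focal <- config$focal_fwhm / (2 * sqrt(2 * log(2)))
  dz_score <- (config$scoring_z - config$focal_z) * CM2MM
  dz_iso <- (100 - config$focal_z) * CM2MM

  ## primary: emitted at the focal spot, aimed into the isocenter window
  y0 <- stats::rnorm(np, 0, sigma_focal)
  aim <- stats::runif(np, -config$aim_window, config$aim_window)
  theta <- atan((aim - y0) / dz_iso) +
    stats::rnorm(np, 0, config$angular_spread / 1000)
  yp <- y0 + tan(theta) * dz_score

  ## secondary: broad spatial spread at the scoring plane, divergent mean
  ## direction from the focal spot, 3x angular noise
  sigma_sec <- config$secondary_spatial_fwhm / (2 * sqrt(2 * log(2)))
  ys <- stats::rnorm(ns, 0, sigma_sec)
  theta_s <- atan(ys / (config$scoring_z * CM2MM)) +
    stats::rnorm(ns, 0, 3 * config$angular_spread / 1000)

  e_p <- sample_spectrum(photon_spectrum(config$primary_mean_energy, "poly"),
                         np)
  e_s <- sample_spectrum(photon_spectrum(config$secondary_mean_energy, "poly",
                                         e_max = 3), ns)

  y <- numeric(n); th <- numeric(n); en <- numeric(n)
  y[is_primary] <- yp;  y[!is_primary] <- ys
  th[is_primary] <- theta; th[!is_primary] <- theta_s
  en[is_primary] <- e_p; en[!is_primary] <- e_s
  photon_records(y = y, z = config$scoring_z, u = sin(th), v = cos(th),
                 energy = en, weight = 1,
                 source = ifelse(is_primary, "primary", "secondary"))
}

## inverse-CDF sampling from a binned spectrum, jittered within bins
sample_spectrum <- function(spectrum, n) {
  if (n == 0) return(numeric(0))
  idx <- sample.int(length(spectrum$energies), n, replace = TRUE,
                    prob = spectrum$probs)
  half_bin <- diff(spectrum$energies[1:2]) / 2
  spectrum$energies[idx] + stats::runif(n, -half_bin, half_bin)
}

#' Read/write photon records in the columnar text format
#'
#' Plain whitespace-separated columns `y z u v energy weight [source]` with
#' a header line.
#'
#' @param records A [photon_records()] table.
#' @param file Path.
#' @return `read_photon_records()` returns a [photon_records()] table.
#' @export
write_photon_records <- function(records, file) {
  utils::write.table(as.data.frame(records), file, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_photon_records
#' @export
read_photon_records <- function(file) {
  df <- utils::read.table(file, header = TRUE)
  photon_records(df$y, df$z, df$u, df$v, df$energy, df$weight,
                 if ("source" %in% names(df)) df$source else NA)
}
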