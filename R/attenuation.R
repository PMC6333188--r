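#' Load the packaged mass-attenuation table for the leaf alloy elements
#'
#' Reads the XCOM-style table of mass attenuation coefficients (total, with
#' coherent scattering) for W, Ni and Fe shipped with the package, and binds
#' it to a leaf material (density and composition).  The mixture rule
#' `mu/rho(mix) = sum_i w_i mu/rho(i)` is applied at evaluation time.
#'
#' @param file Path to a columnar table with columns `energy_MeV` and one
#'   `mu_rho_<element>` column per element.  Defaults to the packaged
#'   tungsten-alloy table (0.05-7 MeV).
#' @param density Material density (g/cm^3).
#' @param composition Named mass-fraction vector; names must match the
#'   `mu_rho_*` columns of the table.
#' @return Object of class `attenuation_table`.
#' @examples
#' tab <- attenuation_table()
#' mu_linear(tab, 1.6)   # linear attenuation coefficient in 1/cm
#' @export
attenuation_table <- function(file = system.file("extdata",
                                                 "mu_over_rho_walloy.tsv",
                                                 package = "vsmlc"),
                              density = 18.5,
                              composition = c(W = 0.96, Ni = 0.03,
                                              Fe = 0.01)) {
  raw <- utils::read.delim(file, comment.char = "#", sep = "\t")
  stopifnot("energy_MeV" %in% names(raw))
  elements <- sub("^mu_rho_", "", grep("^mu_rho_", names(raw), value = TRUE))
  if (!all(names(composition) %in% elements))
    stop("composition contains elements absent from the table: ",
         paste(setdiff(names(composition), elements), collapse = ", "),
         call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-6)
    stop("composition mass fractions must sum to 1", call. = FALSE)
  e <- raw$energy_MeV
  if (any(diff(e) <= 0)) stop("table energies must be strictly increasing",
                              call. = FALSE)
  mu_rho <- as.matrix(raw[grep("^mu_rho_", names(raw))])
  colnames(mu_rho) <- sub("^mu_rho_", "", colnames(mu_rho))
  if (any(mu_rho <= 0)) stop("mu/rho values must be positive", call. = FALSE)
  structure(list(energies = e, mu_over_rho = mu_rho, density = density,
                 composition = composition),
            class = "attenuation_table")
}

#' @export
print.attenuation_table <- function(x, ...) {
  cat(sprintf(
    "Attenuation table: %d energies %.3g-%.3g MeV, elements %s\n",
    length(x$energies), min(x$energies), max(x$energies),
    paste(colnames(x$mu_over_rho), collapse = "/")))
  cat(sprintf("  mixture: %s at %.3g g/cm^3\n",
              paste(sprintf("%s %.3g", names(x$composition), x$composition),
                    collapse = ", "), x$density))
  invisible(x)
}

#' Linear attenuation coefficient of the leaf material
#'
#' Log-log interpolates each element's mass attenuation coefficient at the
#' requested energies, mixes by mass fraction, and multiplies by the
#' material density.  No extrapolation: energies outside the tabulated
#' range raise an error.
#'
#' @param table An [attenuation_table()].
#' @param energy Photon energy (MeV); vectorized.
#' @return Linear attenuation coefficient(s), 1/cm.
#' @export
mu_linear <- function(table, energy) {
  e <- table$energies
  if (any(energy < min(e) | energy > max(e)))
    stop(sprintf("energy outside table range [%.3g, %.3g] MeV",
                 min(e), max(e)), call. = FALSE)
  w <- table$composition
  mix <- numeric(length(energy))
  for (el in names(w)) {
    logmu <- stats::approx(log(e), log(table$mu_over_rho[, el]),
                           xout = log(energy))$y
    mix <- mix + w[[el]] * exp(logmu)
  }
  mix * table$density
}

#' Exponential transmission through a material path
#'
#' @param path_length Path length in the material (cm); vectorized.
#' @param mu Linear attenuation coefficient (1/cm).
#' @return Transmitted fraction `exp(-mu * path_length)`.
#' @examples
#' transmission(0, 1)            # 1
#' transmission(9, mu_linear(attenuation_table(), 1.6))
#' @export
transmission <- function(path_length, mu) {
  if (any(path_length < 0)) stop("path_length must be >= 0", call. = FALSE)
  exp(-mu * path_length)
}

#' Spectrum-weighted transmission
#'
#' Probability-weighted mean of the per-bin exponential transmissions of a
#' polyenergetic spectrum; a monoenergetic spectrum uses the attenuation
#' coefficient at its mean energy.
#'
#' @param table An [attenuation_table()].
#' @param spectrum A [photon_spectrum()].
#' @param path_length Path length(s) in the material (cm).
#' @param mu_scale Optional scale factor applied to the attenuation
#'   coefficient (used by sensitivity scenarios, e.g. 0.75 for a 25%
#'   reduction in leaf attenuation).
#' @return Transmitted fraction(s), same length as `path_length`.
#' @export
spectrum_transmission <- function(table, spectrum, path_length,
                                  mu_scale = 1) {
  if (any(path_length < 0)) stop("path_length must be >= 0", call. = FALSE)
  if (spectrum$type == "mono") {
    mu <- mu_linear(table, spectrum$mean) * mu_scale
    return(exp(-mu * path_length))
  }
  mu <- mu_linear(table, spectrum$energies) * mu_scale
  ## rows: paths, cols: bins
  drop(exp(outer(-path_length, mu)) %*% spectrum$probs)
}

#' Photon energy spectrum
#'
#' Either a monoenergetic line at the mean energy or a binned polyenergetic
#' spectrum with a bremsstrahlung-like shape `p(E) ~ E^alpha exp(-E/beta)`
#' truncated to `[e_min, e_max]`, with `beta` solved numerically so that
#' the binned mean equals `mean_energy`.
#'
#' @param mean_energy Mean photon energy (MeV).
#' @param type `"mono"` or `"poly"`.
#' @param alpha Power-law index of the polyenergetic shape.
#' @param e_min,e_max Spectrum support (MeV).
#' @param n_bins Number of energy bins for the polyenergetic table.
#' @return Object of class `photon_spectrum` with fields `energies` and
#'   `probs` (probabilities summing to 1) for polyenergetic spectra.
#' @examples
#' s <- photon_spectrum(1.6, "poly")
#' sum(s$probs * s$energies)   # 1.6
#' @export
photon_spectrum <- function(mean_energy, type = c("mono", "poly"),
                            alpha = 0.3, e_min = 0.1, e_max = 6,
                            n_bins = 48) {
  type <- match.arg(type)
  if (mean_energy <= 0) stop("mean_energy must be > 0", call. = FALSE)
  if (type == "mono")
    return(structure(list(type = "mono", mean = mean_energy,
                          energies = mean_energy, probs = 1),
                     class = "photon_spectrum"))
  if (mean_energy <= e_min || mean_energy >= e_max)
    stop("mean_energy must lie inside (e_min, e_max)", call. = FALSE)
  mids <- e_min + (seq_len(n_bins) - 0.5) * (e_max - e_min) / n_bins
  binned_mean <- function(beta) {
    p <- mids^alpha * exp(-mids / beta)
    sum(p * mids) / sum(p)
  }
  beta <- stats::uniroot(function(b) binned_mean(b) - mean_energy,
                         interval = c(1e-3, 1e3), tol = 1e-12)$root
  p <- mids^alpha * exp(-mids / beta)
  p <- p / sum(p)
  structure(list(type = "poly", mean = mean_energy, energies = mids,
                 probs = p, alpha = alpha, beta = beta),
            class = "photon_spectrum")
}

#' @export
print.photon_spectrum <- function(x, ...) {
  if (x$type == "mono")
    cat(sprintf("Monoenergetic spectrum at %.3g MeV\n", x$mean))
  else
    cat(sprintf(
      "Polyenergetic spectrum: %d bins on [%.3g, %.3g] MeV, mean %.3g MeV\n",
      length(x$energies), min(x$energies), max(x$energies), x$mean))
  invisible(x)
}
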