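#' Nominal model configuration
#'
#' The fitted nominal configuration of the analytic model: leaf bank
#' rotation 9 mrad, interleaf air gap 0.089 mm, leaf density 18.5 g/cm^3
#' (96/3/1 W/Ni/Fe), primary Gaussian source of FWHM 1.05 mm at
#' Z = 1.1 cm with mean energy 1.6 MeV, secondary source at Z = 15.9 cm
#' with mean energy 0.7 MeV, oblique path tracing, no tongue-and-groove,
#' and a single open leaf centered on the axis ("CCCCCOCCCCC").
#'
#' @param quadrature Source-plane quadrature step (mm).
#' @param grid_step Isocenter grid step (mm).
#' @param grid_half Isocenter grid half-width (mm).
#' @return A `vsm_config` list of plain parameter values; see
#'   [profile_from_config()] to evaluate it.
#' @examples
#' cfg <- nominal_config()
#' cfg$leaf$lbrot
#' @export
nominal_config <- function(quadrature = 0.01, grid_step = 0.1,
                           grid_half = 15) {
  structure(list(
    beam = list(z_target_distal = 1.1, z_filter_distal = 15.9,
                z_mlc_top = 30, z_isocenter = 100, sad = 100),
    leaf = list(projected_width = 5, height = 90, lbrot = 9,
                air_gap = 0.089, tg_enabled = FALSE, tg_width = 0.4,
                density = 18.5,
                composition = c(W = 0.96, Ni = 0.03, Fe = 0.01)),
    aperture = "CCCCCOCCCCC",
    primary = list(type = "gaussian", fwhm = 1.05, radius = NA,
                   mean_energy = 1.6, energy_mode = "mono",
                   angular_type = "focal", angular_spread = 23),
    secondary = list(enabled = TRUE, fwhm = 30, mean_energy = 0.7,
                     energy_mode = "mono", angular_type = "focal",
                     angular_spread = 100, weight = 0.05),
    raytrace = list(path_mode = "oblique", quadrature = quadrature,
                    margin = 5, grid_step = grid_step,
                    grid_half = grid_half),
    mu_scale = 1, attenuate = TRUE), class = "vsm_config")
}

## registry of sweep/scenario parameter names -> config locations
config_parameters <- function() {
  list(lbrot = c("leaf", "lbrot"),
       air_gap = c("leaf", "air_gap"),
       tg_enabled = c("leaf", "tg_enabled"),
       tg_width = c("leaf", "tg_width"),
       density = c("leaf", "density"),
       source_type = c("primary", "type"),
       source_fwhm = c("primary", "fwhm"),
       source_radius = c("primary", "radius"),
       angular_type = c("primary", "angular_type"),
       angular_spread = c("primary", "angular_spread"),
       primary_mean_energy = c("primary", "mean_energy"),
       energy_mode = c("primary", "energy_mode"),
       secondary_mean_energy = c("secondary", "mean_energy"),
       secondary_fwhm = c("secondary", "fwhm"),
       secondary_weight = c("secondary", "weight"),
       secondary_enabled = c("secondary", "enabled"),
       path_mode = c("raytrace", "path_mode"),
       quadrature = c("raytrace", "quadrature"),
       mu_scale = "mu_scale",
       attenuate = "attenuate",
       aperture = "aperture")
}

#' Apply named parameter overrides to a configuration
#'
#' Overrides use short registry names (e.g. `lbrot`, `source_fwhm`,
#' `mu_scale`); unknown names raise an error listing the valid ones.
#' `energy_mode` and `angular_type` are applied to both sources.
#'
#' @param config A `vsm_config`.
#' @param overrides Named list.
#' @return The modified `vsm_config`.
#' @export
apply_overrides <- function(config, overrides) {
  reg <- config_parameters()
  bad <- setdiff(names(overrides), names(reg))
  if (length(bad))
    stop("unknown parameter(s) ", paste(bad, collapse = ", "),
         "; valid names: ", paste(names(reg), collapse = ", "),
         call. = FALSE)
  for (nm in names(overrides)) {
    path <- reg[[nm]]
    if (length(path) == 1) config[[path]] <- overrides[[nm]]
    else config[[path[1]]][[path[2]]] <- overrides[[nm]]
    if (nm == "energy_mode")
      config$secondary$energy_mode <- overrides[[nm]]
    if (nm == "angular_type")
      config$secondary$angular_type <- overrides[[nm]]
  }
  config
}

## materialize the S3 objects described by a config
config_objects <- function(config) {
  geom <- do.call(beam_geometry, config$beam)
  spec <- do.call(leaf_spec, c(config$leaf, list(geom = geom)))
  aperture <- aperture_state(config$aperture)
  p <- config$primary
  spatial <- switch(p$type,
                    gaussian = list(type = "gaussian", fwhm = p$fwhm),
                    point = list(type = "point"),
                    disc = list(type = "disc", radius = p$radius))
  ## the primary weight complements the configured secondary weight even
  ## when the secondary is disabled, so that "exclude the secondary"
  ## removes its contribution instead of renormalizing the primary
  w_s <- config$secondary$weight
  primary <- virtual_source(
    z_source = geom$z_target_distal, spatial = spatial,
    spectrum = photon_spectrum(p$mean_energy, p$energy_mode),
    angular = list(type = p$angular_type, spread = p$angular_spread,
                   window = 10, divergence_origin_z = NULL),
    rel_weight = 1 - w_s)
  sources <- list(primary)
  if (isTRUE(config$secondary$enabled) && w_s > 0) {
    s <- config$secondary
    sources[[2]] <- virtual_source(
      z_source = geom$z_filter_distal,
      spatial = list(type = "gaussian", fwhm = s$fwhm),
      spectrum = photon_spectrum(s$mean_energy, s$energy_mode),
      angular = list(type = s$angular_type, spread = s$angular_spread,
                     window = 70, divergence_origin_z = 0),
      rel_weight = w_s)
  }
  mode <- ray_trace_mode(config$raytrace$path_mode,
                         config$raytrace$quadrature,
                         config$raytrace$margin)
  grid <- seq(-config$raytrace$grid_half, config$raytrace$grid_half,
              by = config$raytrace$grid_step)
  table <- attenuation_table(density = spec$density,
                             composition = spec$composition)
  list(geom = geom, spec = spec, aperture = aperture, sources = sources,
       mode = mode, grid = grid, table = table)
}

#' Evaluate the fluence profile described by a configuration
#'
#' @param config A `vsm_config` (see [nominal_config()]).
#' @param normalize Normalize the profile to unit integral?  Sensitivity
#'   ratios are computed on unnormalized profiles, so the default here is
#'   `FALSE`.
#' @return A `fluence_profile`.
#' @export
profile_from_config <- function(config, normalize = FALSE) {
  ob <- config_objects(config)
  compute_profile(ob$sources, ob$spec, ob$aperture, ob$geom, ob$grid,
                  ob$mode, ob$table, normalize = normalize,
                  mu_scale = config$mu_scale,
                  attenuate = config$attenuate)
}

#' Read/write a model configuration as YAML
#'
#' The YAML file mirrors the [nominal_config()] structure (sections
#' `beam`, `leaf`, `aperture`, `primary`, `secondary`, `raytrace`,
#' optional `generator`); omitted keys keep their nominal defaults.
#'
#' @param file Path to a YAML file.
#' @return `read_config()` returns a `vsm_config`.
#' @export
read_config <- function(file) {
  raw <- yaml::read_yaml(file)
  cfg <- nominal_config()
  for (sec in names(raw)) {
    if (!sec %in% c(names(cfg), "generator"))
      stop("unknown config section: ", sec, call. = FALSE)
    if (is.list(raw[[sec]]) && is.list(cfg[[sec]])) {
      for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
      if (sec == "leaf" && !is.null(raw$leaf$composition))
        cfg$leaf$composition <- unlist(raw$leaf$composition)
    } else {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  cfg
}

#' @rdname read_config
#' @param config A `vsm_config`.
#' @export
write_config <- function(config, file) {
  out <- unclass(config)
  out$leaf$composition <- as.list(out$leaf$composition)
  yaml::write_yaml(out, file)
  invisible(file)
}
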