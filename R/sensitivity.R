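#' Sensitivity scenario
#'
#' A named modification of the nominal configuration.  `overrides` are
#' applied to produce the perturbed model; `ref_overrides` (usually empty)
#' are applied to produce the reference the scenario is compared against,
#' for scenarios whose baseline differs from the shipped nominal model
#' (e.g. a point source, or polyenergetic spectra).
#'
#' @param name Scenario name.
#' @param overrides Named list of parameter overrides (see
#'   [apply_overrides()]).
#' @param ref_overrides Overrides for the reference configuration.
#' @param metric Profile summary the scenario targets: `"max"` or
#'   `"integral"`.
#' @return Object of class `scenario`.
#' @export
scenario <- function(name, overrides, ref_overrides = list(),
                     metric = c("max", "integral")) {
  metric <- match.arg(metric)
  structure(list(name = name, overrides = overrides,
                 ref_overrides = ref_overrides, metric = metric),
            class = "scenario")
}

#' Named scenario presets of the sensitivity study
#'
#' One preset per studied perturbation of the nominal model:
#' \describe{
#'   \item{identity}{no change (ratios 1, DTA 0).}
#'   \item{exclude_secondary}{remove the secondary (head-scatter) source.}
#'   \item{no_attenuation}{100% leaf transmission.}
#'   \item{attenuation_scale_0.75}{attenuation coefficient scaled to 75%.}
#'   \item{point_to_disc2mm}{primary source changed from a point to a
#'     uniform disc of 2 mm radius.}
#'   \item{lbrot_0, lbrot_12}{leaf bank rotation moved off its fitted
#'     9 mrad value.}
#'   \item{tongue_and_groove}{0.4 mm tongue-and-groove step enabled.}
#'   \item{parallel_path}{axis-parallel attenuation paths instead of
#'     oblique rays.}
#'   \item{uniform_angular}{uniform instead of position-dependent angular
#'     emission.}
#'   \item{primary_energy_minus_0.2}{primary mean energy lowered from 1.6
#'     to 1.4 MeV (integral metric).}
#'   \item{mono_vs_poly}{monoenergetic sources at the mean energies
#'     instead of binned polyenergetic spectra.}
#' }
#'
#' @return Named list of [scenario()] objects.
#' @export
scenario_presets <- function() {
  ps <- list(
    scenario("identity", list()),
    scenario("exclude_secondary", list(secondary_enabled = FALSE)),
    scenario("no_attenuation", list(attenuate = FALSE)),
    scenario("attenuation_scale_0.75", list(mu_scale = 0.75)),
    scenario("point_to_disc2mm",
             list(source_type = "disc", source_radius = 2),
             ref_overrides = list(source_type = "point")),
    scenario("lbrot_0", list(lbrot = 0)),
    scenario("lbrot_12", list(lbrot = 12)),
    scenario("tongue_and_groove", list(tg_enabled = TRUE)),
    scenario("parallel_path", list(path_mode = "parallel")),
    scenario("uniform_angular", list(angular_type = "uniform")),
    scenario("primary_energy_minus_0.2",
             list(primary_mean_energy = 1.4), metric = "integral"),
    scenario("mono_vs_poly", list(energy_mode = "mono"),
             ref_overrides = list(energy_mode = "poly")))
  stats::setNames(ps, vapply(ps, function(s) s$name, ""))
}

#' Run one sensitivity scenario
#'
#' Computes the reference and perturbed fluence profiles and compares
#' them.  Ratio metrics use unnormalized fluence: normalizing to unit
#' integral would cancel exactly the integral changes the study looks
#' for.
#'
#' @param scen A [scenario()] or the name of a preset.
#' @param config Base configuration (default [nominal_config()]).
#' @param dta_window Window for the 50% DTA search (mm).
#' @return One-row `data.frame`: `name`, `rel_max_fluence`,
#'   `rel_integral`, `dta_avg` (mm), `pct_max` and `pct_integral`
#'   (percent changes relative to the reference profile).
#' @examples
#' \donttest{
#' run_scenario("identity", nominal_config(quadrature = 0.05,
#'                                         grid_step = 0.25))
#' }
#' @export
run_scenario <- function(scen, config = nominal_config(),
                         dta_window = c(-6, 6)) {
  if (is.character(scen)) {
    ps <- scenario_presets()
    if (!scen %in% names(ps))
      stop("unknown scenario; valid presets: ",
           paste(names(ps), collapse = ", "), call. = FALSE)
    scen <- ps[[scen]]
  }
  ref_cfg <- apply_overrides(config, scen$ref_overrides)
  alt_cfg <- apply_overrides(ref_cfg, scen$overrides)
  ref <- profile_from_config(ref_cfg, normalize = FALSE)
  alt <- if (identical(ref_cfg, alt_cfg)) ref
         else profile_from_config(alt_cfg, normalize = FALSE)
  compare_profiles(scen$name, ref, alt, dta_window)
}

compare_profiles <- function(name, ref, alt, dta_window = c(-6, 6)) {
  rel_max <- profile_max(alt) / profile_max(ref)
  rel_int <- profile_integral(alt) / profile_integral(ref)
  ## profiles without a 50% crossing (e.g. unattenuated, nearly flat
  ## fluence) have no penumbra DTA
  dta <- tryCatch(dta_at_half_max(ref, alt, dta_window)[["avg"]],
                  error = function(e) NA_real_)
  data.frame(name = name, rel_max_fluence = rel_max,
             rel_integral = rel_int, dta_avg = dta,
             pct_max = 100 * (rel_max - 1),
             pct_integral = 100 * (rel_int - 1))
}

#' Sweep one model parameter
#'
#' Recomputes the fluence profile for each parameter value and compares
#' every profile against the profile of the unmodified base
#' configuration, whose parameter value must be among `values` so the
#' table contains the nominal row (ratios exactly 1, DTA 0).
#'
#' @param parameter Registry parameter name (see [apply_overrides()]).
#' @param values Vector of parameter values including the nominal one.
#' @param config Base configuration.
#' @param dta_window Window for the 50% DTA search (mm).
#' @return `data.frame` with one row per value: `parameter`, `value`,
#'   `rel_max_fluence`, `rel_integral`, `dta_avg`.
#' @examples
#' \donttest{
#' run_sweep("lbrot", c(0, 9, 12),
#'           nominal_config(quadrature = 0.05, grid_step = 0.25))
#' }
#' @export
run_sweep <- function(parameter, values, config = nominal_config(),
                      dta_window = c(-6, 6)) {
  reg <- config_parameters()
  if (!parameter %in% names(reg))
    stop("unknown parameter '", parameter, "'; valid names: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  if (length(values) < 2)
    stop("need at least two sweep values", call. = FALSE)
  path <- reg[[parameter]]
  nominal_value <- if (length(path) == 1) config[[path]]
                   else config[[path[1]]][[path[2]]]
  if (!any(vapply(values, identical, NA, nominal_value) |
           vapply(values, function(v) isTRUE(all.equal(v, nominal_value)),
                  NA)))
    stop("sweep values must include the nominal value (",
         format(nominal_value), ")", call. = FALSE)
  ref <- profile_from_config(config, normalize = FALSE)
  rows <- lapply(values, function(v) {
    cfg <- apply_overrides(config, stats::setNames(list(v), parameter))
    alt <- if (isTRUE(all.equal(v, nominal_value))) ref
           else profile_from_config(cfg, normalize = FALSE)
    cbind(data.frame(parameter = parameter,
                     value = if (is.numeric(v)) v else as.character(v)),
          compare_profiles("sweep", ref, alt, dta_window)[
            , c("rel_max_fluence", "rel_integral", "dta_avg")])
  })
  do.call(rbind, rows)
}
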