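## fast configuration for property tests: coarser quadrature and grid than
## the study defaults, converged well past the tolerances asserted here
fast_config <- function(...) {
  cfg <- nominal_config(quadrature = 0.05, grid_step = 0.25)
  over <- list(...)
  if (length(over)) cfg <- apply_overrides(cfg, over)
  cfg
}

## simple wide slab "MLC": one closed leaf spanning the whole field
slab_bank <- function(height = 90, lbrot = 0, z_mlc_top = 30) {
  geom <- beam_geometry(z_mlc_top = z_mlc_top)
  spec <- leaf_spec(projected_width = 200, height = height, lbrot = lbrot,
                    air_gap = 0, geom = geom)
  list(polys = build_leaf_bank(spec, aperture_state("C"), geom),
       geom = geom, spec = spec)
}

## analytic gaussian test profile
gaussian_profile <- function(center = 0, sigma = 2, grid = seq(-8, 8, 0.1),
                             scale = 1) {
  fluence_profile(grid, scale * exp(-(grid - center)^2 / (2 * sigma^2)))
}

## brute-force double-loop gamma oracle (no interpolation)
gamma_oracle <- function(reference, evaluated, criteria) {
  dmax <- max(reference$values)
  vapply(seq_along(reference$y_grid), function(i) {
    min(sqrt(((evaluated$y_grid - reference$y_grid[i]) /
                criteria$dist_tol)^2 +
             ((evaluated$values - reference$values[i]) /
                (criteria$dose_tol / 100 * dmax))^2))
  }, 0)
}
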