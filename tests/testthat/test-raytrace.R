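geom <- beam_geometry()

test_that("path lengths through slabs match closed-form geometry", {
  sl <- slab_bank()
  ## axis-parallel ray through the unrotated slab: exactly the leaf height
  expect_equal(path_length(0, 1.1, 0, sl$polys, geom = sl$geom), 9)
  ## oblique ray fully inside the slab: h / cos(theta)
  m <- (20 - (-10)) / ((100 - 1.1) * 10)
  expect_equal(path_length(-10, 1.1, 20, sl$polys, geom = sl$geom),
               9 * sqrt(1 + m^2))
  ## parallel mode reduces the same ray to the vertical chord
  expect_equal(path_length(-10, 1.1, 20, sl$polys,
                           ray_trace_mode("parallel"), sl$geom), 9)
  ## ray through an open leaf gap: zero
  bank <- build_leaf_bank(leaf_spec(lbrot = 0), aperture_state("COC"), geom)
  expect_equal(path_length(0, 1.1, 0, bank, geom = geom), 0)
  ## missing all polygons
  expect_equal(path_length(0, 1.1, 200, bank, geom = geom), 0)
})

test_that("rotated-leaf path lengths interpolate between 0 and full height", {
  bank <- build_leaf_bank(leaf_spec(lbrot = 9), aperture_state("COC"), geom)
  ## scan vertical rays across the wedge at the aperture edge
  ys <- seq(-2, 2, 0.01)
  p <- vapply(ys, function(y)
    path_length(y * 0.345, 0, y, bank,
                ray_trace_mode("parallel"), geom), 0)
  expect_true(all(p >= 0 & p <= 9 + 1e-9))
  expect_true(any(p == 0) && any(p > 8.9))
  expect_true(any(p > 0.5 & p < 8.5))   # partial wedge chords exist
})

test_that("source boundaries cover the emission support plus margin", {
  pt <- virtual_source(1.1, list(type = "point"), photon_spectrum(1.6),
                       list(type = "uniform", window = 10), 1)
  expect_equal(source_boundaries(pt, margin = 5), c(-5, 5))
  g <- primary_source(rel_weight = 1)
  b <- source_boundaries(g, margin = 5)
  expect_equal(b[2], 5 * 1.05 / (2 * sqrt(2 * log(2))) + 5)
})

test_that("widening the margin never decreases fluence", {
  cfg5 <- fast_config()
  prof5 <- profile_from_config(cfg5, normalize = FALSE)
  cfg10 <- fast_config()
  cfg10$raytrace$margin <- 10
  prof10 <- profile_from_config(cfg10, normalize = FALSE)
  ## up to the (converged) quadrature-step difference between the two
  ## node sets, more margin can only add emission
  expect_true(all(prof10$values >=
                    prof5$values - 2e-4 * max(prof5$values)))
  expect_gte(profile_integral(prof10),
             profile_integral(prof5) * (1 - 1e-5))
})

test_that("degenerate limits: open field is flat, opaque slab is dark", {
  pt <- virtual_source(1.1, list(type = "point"), photon_spectrum(1.6),
                       list(type = "uniform", window = 10), 1)
  f <- vapply(c(-5, 0, 5), function(y)
    fluence_at_point(y, pt, list(), geom), 0)
  expect_equal(f[1], f[2])
  expect_equal(f[2], f[3])
  sl <- slab_bank()
  expect_equal(fluence_at_point(0, pt, sl$polys, sl$geom,
                                mu_scale = 1e6), 0)
})

test_that("quadrature is converged: halving the step changes the peak <0.1%", {
  src <- primary_source(rel_weight = 1)
  bank <- build_leaf_bank(leaf_spec(), aperture_state("CCCOCCC"), geom)
  f1 <- fluence_at_point(1.2, src, bank, geom,
                         ray_trace_mode(quadrature = 0.04))
  f2 <- fluence_at_point(1.2, src, bank, geom,
                         ray_trace_mode(quadrature = 0.02))
  expect_lt(abs(f2 / f1 - 1), 0.001)
})

test_that("too-coarse quadrature warns", {
  src <- primary_source(rel_weight = 1)
  expect_warning(
    fluence_at_point(0, src, list(), geom,
                     ray_trace_mode(quadrature = 0.2)),
    "coarse")
})

test_that("profiles normalize to unit integral and compose linearly", {
  cfg <- fast_config()
  prof <- profile_from_config(cfg, normalize = TRUE)
  expect_equal(profile_integral(prof), 1, tolerance = 1e-6)
  expect_true(all(prof$values >= 0))

  ## a zero-weight secondary changes nothing
  ob <- vsmlc:::config_objects(cfg)
  both <- compute_profile(ob$sources, ob$spec, ob$aperture, ob$geom,
                          ob$grid, ob$mode, ob$table, normalize = FALSE)
  ob$sources[[1]]$rel_weight <- 1
  ob$sources[[2]]$rel_weight <- 1
  prim <- compute_profile(ob$sources[1], ob$spec, ob$aperture, ob$geom,
                          ob$grid, ob$mode, ob$table, normalize = FALSE)
  sec <- compute_profile(ob$sources[2], ob$spec, ob$aperture, ob$geom,
                         ob$grid, ob$mode, ob$table, normalize = FALSE)
  expect_equal(both$values, 0.95 * prim$values + 0.05 * sec$values,
               tolerance = 1e-12)
})

test_that("a point source through one open leaf gives a sharp top-hat", {
  cfg <- fast_config(source_type = "point", angular_type = "uniform",
                     air_gap = 0, lbrot = 0, secondary_enabled = FALSE)
  cfg$raytrace$grid_step <- 0.05
  prof <- profile_from_config(cfg)
  v <- prof$values / max(prof$values)
  y <- prof$y_grid
  width50 <- diff(range(y[v >= 0.5]))
  ## flat (unfocused) leaf sides: the point-source field edge lies
  ## between the shadows of the inner bottom corner (0.8625 mm * 989/379
  ## = 2.25 mm) and the inner top corner (2.95 mm); the 50% level sits
  ## just inside the bottom-corner shadow, so the width is close to the
  ## nominal 5 mm projected opening but bounded by the corner shadows
  expect_gt(width50, 2 * 2.20)
  expect_lt(width50, 2 * 2.95)
  ## penumbra collapses to the grid scale in the point-source limit
  rise <- diff(range(y[v >= 0.2 & v <= 0.8 & y < 0]))
  expect_lte(rise, 0.1 + 1e-9)
})

test_that("disabling attenuation never decreases fluence", {
  cfg <- fast_config()
  on <- profile_from_config(cfg, normalize = FALSE)
  cfg_off <- fast_config(attenuate = FALSE)
  off <- profile_from_config(cfg_off, normalize = FALSE)
  expect_true(all(off$values >= on$values - 1e-12))
})

test_that("the profile is symmetric without bank rotation", {
  cfg <- fast_config(lbrot = 0)
  prof <- profile_from_config(cfg, normalize = FALSE)
  expect_equal(prof$values, rev(prof$values),
               tolerance = 1e-9)
})

test_that("fully opaque closed fields raise the all-zero error", {
  cfg <- fast_config(aperture = "CCCCCCCCC", secondary_enabled = FALSE,
                     mu_scale = 1e4, air_gap = 0)
  cfg$raytrace$grid_half <- 2
  expect_error(profile_from_config(cfg), "all-zero")
})

test_that("profile files round-trip including metadata", {
  prof <- gaussian_profile()
  prof$meta <- list(note = "fixture")
  f <- tempfile(fileext = ".csv")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$y_grid, prof$y_grid)
  expect_equal(back$values, prof$values, tolerance = 1e-12)
  expect_equal(back$meta$note, "fixture")
  expect_error(fluence_profile(1:3, c(2, 2, 2), normalized = TRUE),
               "integral")
})
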