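test_that("leaf-bank shift follows the closed form and its limits", {
  expect_equal(mlc_shift(90, 9), 90 * sin(0.009) / 2)
  expect_equal(mlc_shift(90, 9), 0.405, tolerance = 2e-4)
  expect_identical(mlc_shift(57, 0), 0)
  expect_equal(mlc_shift(90, 12), 0.54, tolerance = 1e-3)
  expect_error(mlc_shift(-1, 9), "invalid geometry")

  ## monotone in both arguments
  shifts_h <- vapply(seq(10, 150, 20), mlc_shift, 0, lbrot = 9)
  shifts_a <- vapply(seq(0, 12, 2), mlc_shift, 0, height = 90)
  expect_true(all(diff(shifts_h) > 0))
  expect_true(all(diff(shifts_a) > 0))

  ## small-angle limit within 0.01% up to 12 mrad
  for (a in c(3, 9, 12))
    expect_equal(mlc_shift(90, a), 90 * (a / 1000) / 2,
                 tolerance = 1e-4)
})

test_that("divergent projection is exact and linear", {
  expect_equal(project_to_isocenter(c(0, 50), 0), 0)
  expect_equal(project_to_isocenter(c(1, 50), 0), 2)
  ## linearity in the in-line coordinate
  y <- c(0.3, 1.7)
  p <- project_to_isocenter(cbind(y, 40), 0)
  expect_equal(p[2] / p[1], y[2] / y[1])
  ## pitch derivation consistency: a leaf edge at half pitch at the MLC
  ## mid-plane projects to half the projected width
  spec <- leaf_spec()
  expect_equal(project_to_isocenter(c(spec$physical_pitch / 2,
                                      spec$z_mlc_mid), 0),
               spec$projected_width / 2)
  expect_error(project_to_isocenter(c(1, -2), 0), "upstream")
})

test_that("beam geometry and leaf spec validate their invariants", {
  expect_error(beam_geometry(z_mlc_top = 5), "invalid beam geometry")
  expect_error(leaf_spec(height = -1), "height")
  expect_error(leaf_spec(composition = c(W = 0.9, Ni = 0.2)), "sum to 1")
  expect_error(leaf_spec(tg_width = 5), "tg_width")
  expect_error(aperture_state("OXC"), "O")
  expect_equal(aperture_state("COC")$leaf_open, c(FALSE, TRUE, FALSE))
})

test_that("unrotated gap-free bank tiles the in-line axis", {
  geom <- beam_geometry()
  spec <- leaf_spec(lbrot = 0, air_gap = 0, geom = geom)
  bank <- build_leaf_bank(spec, aperture_state("CCCCC"), geom)
  expect_length(bank, 5)
  for (k in 1:4) {
    right <- bank[[k]]$quads[1, "y_right"]
    left <- bank[[k + 1]]$quads[1, "y_left"]
    expect_equal(unname(right), unname(left))
  }
  ## rectangles: zero slant, width = pitch
  for (p in bank) {
    expect_equal(unname(p$quads[1, "slant"]), 0)
    expect_equal(unname(p$quads[1, "y_right"] - p$quads[1, "y_left"]),
                 spec$physical_pitch)
  }
})

test_that("rotation shifts every leaf centroid by the bank shift", {
  geom <- beam_geometry()
  ap <- aperture_state("CCOCC")
  bank0 <- build_leaf_bank(leaf_spec(lbrot = 0, geom = geom), ap, geom)
  bank9 <- build_leaf_bank(leaf_spec(lbrot = 9, geom = geom), ap, geom)
  shift <- mlc_shift(90, 9)
  for (k in seq_along(bank0))
    expect_equal(leaf_centroid(bank9[[k]])[["y"]],
                 leaf_centroid(bank0[[k]])[["y"]] + shift)
})

test_that("all-open aperture yields an empty bank; overlap is rejected", {
  geom <- beam_geometry()
  expect_length(build_leaf_bank(leaf_spec(), aperture_state("OOO"), geom), 0)
  bank <- build_leaf_bank(leaf_spec(), aperture_state("CC"), geom)
  bank[[2]]$quads[, c("y_left", "y_right")] <-
    bank[[2]]$quads[, c("y_left", "y_right")] - 1
  expect_error(vsmlc:::check_leaf_overlap(bank), "overlap")
})
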