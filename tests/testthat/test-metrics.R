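test_that("DTA of identical and translated profiles is exact", {
  p <- gaussian_profile()
  expect_equal(dta_at_half_max(p, p),
               c(left = 0, right = 0, avg = 0))
  ## pure translation: both sides equal the shift
  q <- gaussian_profile(center = 0.5)
  d <- dta_at_half_max(p, q)
  expect_equal(d[["left"]], 0.5, tolerance = 1e-9)
  expect_equal(d[["right"]], 0.5, tolerance = 1e-9)
  expect_equal(d[["avg"]], 0.5, tolerance = 1e-9)
  ## avg is the mean of the sides for asymmetric distortions
  r <- fluence_profile(p$y_grid, p$values^1.3)
  d2 <- dta_at_half_max(p, r)
  expect_equal(d2[["avg"]], (d2[["left"]] + d2[["right"]]) / 2)
})

test_that("missing half-max crossings name the failing side", {
  y <- seq(0, 5, 0.1)
  falling <- fluence_profile(y, 5 - y + 0.01)   # peak at the edge: no
  full <- gaussian_profile()                    # left flank to cross
  expect_error(dta_at_half_max(full, falling), "left side")
})

test_that("gamma matches the brute-force oracle and its invariances", {
  set.seed(21)
  ref <- gaussian_profile()
  ev <- fluence_profile(ref$y_grid,
                        pmax(0, ref$values * (1 + stats::rnorm(
                          length(ref$values), 0, 0.02)) ))
  cr <- gamma_criteria(2, 1)
  g <- gamma_1d(ref, ev, cr, refine = FALSE)
  expect_equal(g$gamma, gamma_oracle(ref, ev, cr), tolerance = 1e-9)
  ## refinement can only lower gamma
  gr <- gamma_1d(ref, ev, cr, refine = TRUE)
  expect_true(all(gr$gamma <= g$gamma + 1e-12))
  ## identical profiles: gamma 0, 100% pass
  g0 <- gamma_1d(ref, ref, cr)
  expect_equal(max(g0$gamma), 0)
  expect_equal(g0$pass_rate, 100)
  ## global rescaling of both profiles leaves gamma unchanged
  ref2 <- fluence_profile(ref$y_grid, ref$values * 7.3)
  ev2 <- fluence_profile(ev$y_grid, ev$values * 7.3)
  expect_equal(gamma_1d(ref2, ev2, cr)$gamma, gr$gamma)
  ## looser dose criterion never lowers the pass rate
  expect_gte(gamma_1d(ref, ev, gamma_criteria(2, 1))$pass_rate,
             gamma_1d(ref, ev, gamma_criteria(1, 1))$pass_rate)
  expect_error(gamma_1d(ref, fluence_profile(ref$y_grid + 100,
                                             ref$values), cr),
               "overlap")
})

test_that("a uniform dose offset at the tolerance sits on the gamma boundary", {
  y <- seq(-5, 5, 0.1)
  flat <- fluence_profile(y, rep(1, length(y)))
  up <- fluence_profile(y, rep(1 + 0.02, length(y)))
  g <- gamma_1d(flat, up, gamma_criteria(2, 1))
  expect_equal(max(abs(g$gamma - 1)), 0, tolerance = 1e-9)
  expect_equal(g$pass_rate, 100)
})

test_that("percent difference and absolute dose follow their formulas", {
  expect_equal(percent_difference(100, 100), 0)
  expect_equal(percent_difference(100, 104.3), 4.3)
  a <- 73.2; b <- 81.9
  expect_equal(percent_difference(a, b) * a,
               -percent_difference(b, a) * b)
  expect_error(percent_difference(0, 1), "non-zero")

  expect_equal(absolute_dose(calibration_context(2e-17, 2e-17, 100)), 100)
  ctx <- calibration_context(3.1e-17, 2.5e-17, 150, 1)
  expect_equal(absolute_dose(ctx), 3.1e-17 / 2.5e-17 * 150)
  half <- calibration_context(3.1e-17 / 2, 2.5e-17, 150, 1)
  expect_equal(absolute_dose(half), absolute_dose(ctx) / 2)
  expect_error(calibration_context(1, 0, 100), "> 0")
})

test_that("metric reports assemble the comparison summary", {
  ref <- gaussian_profile()
  ev <- gaussian_profile(center = 0.2, scale = 1.01)
  rep <- metric_report(ref, ev)
  expect_equal(rep$dta_avg, 0.2, tolerance = 1e-6)
  expect_equal(rep$max_value, 1.01, tolerance = 1e-6)
  expect_named(rep$gamma_pass_rate, c("1%/1mm", "2%/1mm"))
  expect_gte(rep$gamma_pass_rate[["2%/1mm"]],
             rep$gamma_pass_rate[["1%/1mm"]])
  expect_output(print(rep), "DTA")
})

test_that("extrema summaries mirror alternating-field reporting", {
  y <- seq(-12, 12, 0.1)
  base <- 0.1 + cos(y * pi / 5)^2
  ref <- fluence_profile(y, base)
  ev <- fluence_profile(y, base * 1.05)
  s <- extrema_differences(ref, ev, centers = c(-10, 0, 10),
                           half_width = 2.5, type = "maxima")
  expect_equal(s$mean, 5, tolerance = 1e-9)
  expect_equal(s$sd, 0, tolerance = 1e-9)
})
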