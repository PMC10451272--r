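test_that("all analytic fixtures self-verify", {
  expect_true(pe_cached("poiseuille_check",
                        fixture_check(make_poiseuille_case()))$pass)
  expect_true(fixture_check(make_beer_lambert_case(n_photons = 5e4))$pass)
  expect_true(pe_cached("slab_check",
                        fixture_check(make_heated_slab_case()))$pass)
})

test_that("Beer-Lambert fixture identities hold", {
  # zero thickness transmits everything
  z <- make_beer_lambert_case(thickness = 0)
  expect_identical(z$runner()$transmitted, 1)
  # doubling mu_a squares the transmitted fraction (exponential identity)
  c1 <- make_beer_lambert_case(mu_a = 1.56)
  c2 <- make_beer_lambert_case(mu_a = 3.12)
  expect_equal(c2$exact$transmitted, c1$exact$transmitted^2)
  # and the Monte Carlo runs agree with that within 3 sigma each
  o1 <- c1$runner(); o2 <- c2$runner()
  expect_lt(abs(o1$transmitted - c1$exact$transmitted), 3 * o1$se)
  expect_lt(abs(o2$transmitted - c2$exact$transmitted), 3 * o2$se)
})

test_that("zero-flow and zero-source fixture limits are exact", {
  p0 <- make_poiseuille_case()
  expect_identical(p0$exact$profile(c(0, 1)), c(0, 0))   # no-slip ends
  s0 <- make_heated_slab_case(q = 0)
  expect_identical(s0$exact$dT_max, 0)
})

test_that("the reduced device is geometrically similar with reported groups", {
  sp <- device_spec(5)
  red <- make_reduced_device(sp, scale = 1, resolution = 2)
  expect_equal(red$spec$chamber_length, sp$chamber_length)   # identity
  half <- make_reduced_device(sp, scale = 0.5, resolution = 4)
  # footprint area scales as scale^2 at fixed height
  expect_equal(footprint_area(half$spec), footprint_area(sp) / 4)
  expect_equal(priming_volume(half$spec), priming_volume(sp) / 4)
  expect_true(all(c("Re_tube", "Pe_chamber") %in%
                  names(half$dimensionless)))
  expect_true(all(half$dimensionless > 0))
  # grid rasterization converges to the scaled footprint (order ~ 1)
  exact <- priming_volume(half$spec)
  e <- vapply(c(2, 8), function(res) {
    g <- suppressWarnings(build_grid(half$spec, res, include_shell = FALSE))
    abs(grid_blood_volume(g) - exact)
  }, numeric(1))
  expect_lt(e[2], e[1])
})
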