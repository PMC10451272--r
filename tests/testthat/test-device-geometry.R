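test_that("footprint area matches the closed form and a rasterization oracle", {
  g1 <- device_spec(0); g2 <- device_spec(5); g3 <- device_spec(10)
  expect_identical(footprint_area(g1), 400)
  expect_equal(footprint_area(g2), 400 - (4 - pi) * 25)
  expect_equal(footprint_area(g3), 100 * pi)
  # independent oracle: rasterized corner-circle test
  for (r in c(0, 5, 10)) {
    sp <- device_spec(r)
    expect_equal(footprint_area(sp), raster_area_oracle(20, 20, r),
                 tolerance = 5e-3)
  }
  # monotone decreasing in fillet radius
  areas <- vapply(seq(0, 10, by = 1),
                  function(r) footprint_area(device_spec(r)), numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("invalid geometries are rejected", {
  expect_error(device_spec(11), "invalid-geometry")
  expect_error(device_spec(0, chamber_height = -1), "invalid-geometry")
  # port forced outside the footprint
  expect_error(device_spec(10, port_scaling_factor = 0), "invalid-geometry")
})

test_that("priming volume reproduces the fiber-adjusted blood volumes", {
  fib <- fiber_mat_spec()     # Oxyphan-style 50/280: 0.038 cm OD, 20/cm, 20 layers
  expect_identical(priming_volume(device_spec(0)), 400)
  v <- vapply(0:2, function(i) priming_volume(device_preset(i + 1), fib),
              numeric(1))
  expect_equal(v, c(219, 208, 171), tolerance = 2 / 171)
  # chord-summation option agrees with the area method closely
  v_ch <- priming_volume(device_spec(5), fib, method = "chords")
  expect_equal(v_ch, v[2], tolerance = 1e-3)
  # fiber mats always reduce the blood volume
  for (r in c(0, 5, 10))
    expect_lt(priming_volume(device_spec(r), fib),
              priming_volume(device_spec(r)))
})

test_that("port positions follow the inset-plus-scaled-fillet rule", {
  p0 <- port_positions(device_spec(0))
  expect_equal(unname(p0$inlet), c(1.2, 1.2))
  expect_equal(unname(p0$outlet), c(18.8, 18.8))
  # degenerate scaling factor: identical to the square placement (small
  # fillet, where the unshifted port still clears the corner arc; for 5 cm
  # fillets an unshifted port disc would leave the footprint and is rejected)
  p2 <- port_positions(device_spec(2, port_scaling_factor = 0))
  expect_equal(p2$inlet, p0$inlet)
  expect_error(device_spec(5, port_scaling_factor = 0), "invalid-geometry")
  # generic scaling: inset 1.2 + 5 s, and the port disc stays inside the
  # footprint (signed-distance predicate)
  s <- 0.4
  sp <- device_spec(5, port_scaling_factor = s)
  pp <- port_positions(sp)
  expect_equal(unname(pp$inlet), rep(1.2 + 5 * s, 2))
  th <- seq(0, 2 * pi, length.out = 33)
  rim_sd <- footprint_sdf(sp, pp$inlet[1] + 0.635 * cos(th),
                          pp$inlet[2] + 0.635 * sin(th))
  expect_true(all(rim_sd < 0))
  # diagonal symmetry: inlet and outlet map onto each other
  expect_equal(unname(pp$outlet),
               c(sp$chamber_length, sp$chamber_width) - unname(pp$inlet))
})

test_that("structured grids capture the blood volume and respect the footprint", {
  sp <- device_spec(10)
  exact <- footprint_area(sp) * sp$chamber_height
  errs <- vapply(c(2, 4, 8), function(res) {
    gr <- suppressWarnings(build_grid(sp, res, include_shell = FALSE))
    # no blood cells outside the filleted footprint
    M <- gr$mask[, , 1] == 1L
    idx <- which(M, arr.ind = TRUE)
    expect_true(all(in_footprint(sp, gr$xc[idx[, 1]], gr$yc[idx[, 2]])))
    abs(grid_blood_volume(gr) - exact)
  }, numeric(1))
  # first-order convergence: error bounded by perimeter x cell size, and
  # decreasing under refinement
  per <- 2 * (20 + 20)
  expect_true(all(errs < per * sp$chamber_height * 1 / c(2, 4, 8)))
  expect_lt(errs[3], errs[1])
  # working resolution captures the volume within 2%
  gr10 <- suppressWarnings(build_grid(device_spec(0), 10, nz_blood = 2,
                                      include_shell = FALSE))
  expect_equal(grid_blood_volume(gr10), 400, tolerance = 0.02)
})

test_that("grid masks include the plexiglass shell around the chamber", {
  gr <- suppressWarnings(build_grid(device_spec(5), 2))
  expect_setequal(unique(as.vector(gr$mask)), c(0L, 1L, 2L))
  # a cell just outside the footprint mid-height must be plexiglass
  k <- gr$kz_blood[length(gr$kz_blood) %/% 2]
  i_out <- which(gr$xc > -1 & gr$xc < 0)[1]
  j_mid <- which.min(abs(gr$yc - 10))
  expect_identical(gr$mask[i_out, j_mid, k], 2L)
  # bottom-most layer under the chamber is plexiglass too
  i_mid <- which.min(abs(gr$xc - 10))
  expect_identical(gr$mask[i_mid, j_mid, 1], 2L)
})

test_that("device specs round-trip through YAML including shipped presets", {
  f <- tempfile(fileext = ".yaml")
  sp <- device_spec(5, port_scaling_factor = 0.25)
  write_device_yaml(sp, f)
  expect_equal(read_device_yaml(f), sp)
  shipped <- system.file("extdata", "geometry2.yaml", package = "photoecmo")
  expect_equal(read_device_yaml(shipped)$fillet_radius, 5)
})
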