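test_that("Carreau viscosity hits its limits and closed-form values", {
  rh <- blood_rheology()
  expect_identical(carreau_viscosity(0, rh), 0.056)
  expect_equal(carreau_viscosity(1e12, rh), 0.0035, tolerance = 1e-6)
  # independent re-implementation at gdot = 1/lambda
  gd <- 1 / rh$lambda
  oracle <- 0.0035 + (0.056 - 0.0035) * (1 + (3.313 * gd)^2)^((0.3568 - 1) / 2)
  expect_equal(carreau_viscosity(gd, rh), oracle)
  expect_equal(oracle, 0.0035 + (0.056 - 0.0035) * 2^((0.3568 - 1) / 2))
  # monotone decreasing
  gds <- 10^seq(-3, 5, length.out = 50)
  expect_true(all(diff(carreau_viscosity(gds, rh)) < 0))
  expect_error(carreau_viscosity(-1, rh), ">= 0")
})

test_that("the Newtonian plane-channel solve recovers Poiseuille flow", {
  chk <- pe_cached("poiseuille_check", fixture_check(make_poiseuille_case()))
  expect_true(chk$pass)
  expect_equal(chk$output$max_over_mean, 1.5, tolerance = 0.02)
  # mid-channel pressure gradient vs 12 mu Q / (w h^3) (finite width adds
  # ~2% side-wall drag at aspect ratio 40)
  expect_equal(chk$output$dpdx, chk$exact$dpdx, tolerance = 0.05)
  # profile shape matches the exact parabola pointwise
  prof <- chk$output$profile
  nz <- length(prof)
  zf <- (seq_len(nz) - 0.5) / nz
  ub <- mean(prof)
  expect_equal(prof / ub, 6 * zf * (1 - zf), tolerance = 0.02)
})

test_that("mean tube velocities follow Q over bore area", {
  sp <- device_spec(0)
  v <- vapply(c(0.25, 1, 3), tube_mean_velocity, numeric(1), spec = sp)
  expect_equal(v, c(32.95, 132.13, 396.72), tolerance = 0.02)
  # resolved duct solve at >= 8 cells across the bore agrees within 5%
  r8 <- solve_tube_flow(1, n_across = 8)
  expect_equal(r8$mean_mm_s, 132.13, tolerance = 0.05)
  expect_gt(r8$max_mm_s, r8$mean_mm_s)
  # finer rasterization converges toward the analytic value
  r24 <- solve_tube_flow(1, n_across = 24)
  expect_lt(abs(r24$mean_mm_s - 131.6), abs(r8$mean_mm_s - 131.6) + 1e-9)
})

test_that("device flow is divergence-free with bounded viscosity", {
  ff <- small_flow(0.1)
  expect_true(ff$converged)
  expect_lt(flow_divergence(ff), 1e-6)
  rh <- blood_rheology()
  expect_true(all(ff$mu >= rh$mu_inf - 1e-12 & ff$mu <= rh$mu0 + 1e-12))
  m <- flow_metrics(ff)
  expect_gte(m$max_chamber_mm_s, m$avg_chamber_mm_s)
  expect_gte(m$avg_chamber_mm_s, 0)
})

test_that("pressure drop rises strictly with flow rate", {
  dps <- vapply(c(0.1, 0.4, 1.2), function(r)
    flow_metrics(small_flow(r))$dp_total_Pa, numeric(1))
  expect_true(all(diff(dps) > 0))
})

test_that("the solved field has the point-reflection port-swap symmetry", {
  # reflecting through the device centre (x, y and z all flipped) maps the
  # inlet onto the outlet; composing that reflection with flow reversal is a
  # symmetry of the Stokes problem, and since both the reflection Jacobian
  # and the reversal flip every component, the cell-centred velocity field
  # must be invariant: v(P(x)) = v(x)
  ff <- small_flow(0.1, inertia = FALSE)
  rot <- function(a) a[rev(seq_len(dim(a)[1])), rev(seq_len(dim(a)[2])),
                       rev(seq_len(dim(a)[3])), drop = FALSE]
  sc <- max(abs(ff$Uc))
  expect_lt(max(abs(ff$Uc - rot(ff$Uc))) / sc, 1e-6)
  expect_lt(max(abs(ff$Vc - rot(ff$Vc))) / sc, 1e-6)
  expect_lt(max(abs(ff$Wc - rot(ff$Wc))) / sc, 1e-6)
})

test_that("chamber averages are grid-insensitive near the working resolution", {
  a3 <- flow_metrics(small_flow(0.1, resolution = 3))$avg_chamber_mm_s
  a4 <- flow_metrics(small_flow(0.1, resolution = 4))$avg_chamber_mm_s
  expect_equal(a3, a4, tolerance = 0.05)
})

test_that("disconnected or invalid flow setups raise errors", {
  sp <- small_device()
  gr <- suppressWarnings(build_grid(sp, 2, nz_blood = 4,
                                    include_shell = FALSE))
  grs <- suppressWarnings(build_grid(sp, 2, nz_blood = 4))
  expect_error(solve_flow(grs, blood_rheology(), flow_bc(0.1)),
               "include_shell")
  expect_error(flow_bc(-1))
})
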