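test_that("absorption-only transport reproduces Beer-Lambert", {
  n <- 1e5
  k <- pe_cached("kernel_mua_only",
    run_photon_transport(optical_properties(1.56, 0, 0),
                         beam_spec(profile = "flat"), n, seed = 3,
                         dr = 0.01, dz = 0.01))
  p <- exp(-1.56)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(k$totals$transmitted - p), 3 * se)
  # depth profile: deposition per depth bin decays exponentially at rate mu_a
  prof <- colSums(k$dep)[1:100]
  zmid <- (seq_len(100) - 0.5) * k$dz
  fit <- stats::lm(log(prof) ~ zmid)
  expect_equal(unname(stats::coef(fit)[2]), -1.56, tolerance = 0.02)
  # 1/e on-axis depth for mu_a = 1.56 is ~0.64 cm
  expect_equal(-1 / unname(stats::coef(fit)[2]), 1 / 1.56, tolerance = 0.02)
  # monotone non-increasing deposition with depth (no scattering); checked
  # on 1 mm aggregates so Monte Carlo noise cannot flip neighbouring bins
  prof_mm <- rowsum(prof, rep(1:10, each = 10))[, 1]
  expect_true(all(diff(prof_mm) < 0))
})

test_that("the photon weight ledger is closed to machine precision", {
  for (op in list(optical_properties(1.56, 0, 0),
                  optical_properties(1.56, 12, 0),
                  optical_properties(1.56, 40, 0.9))) {
    k <- run_photon_transport(op, beam_spec(), 2e4, seed = 5,
                              dr = 0.01, dz = 0.01)
    s <- with(k$totals, absorbed + transmitted + reflected + residual +
                roulette_net)
    expect_lt(abs(s - 1), 1e-12)
    expect_true(all(k$dep >= 0))
  }
})

test_that("scattering runs are seed-reproducible and statistically stable", {
  op <- optical_properties(1.56, 12, 0)
  k1 <- run_photon_transport(op, beam_spec(), 2e4, seed = 9, dr = 0.01,
                             dz = 0.01)
  k1b <- run_photon_transport(op, beam_spec(), 2e4, seed = 9, dr = 0.01,
                              dz = 0.01)
  expect_identical(k1$dep, k1b$dep)          # deterministic given seed
  k2 <- run_photon_transport(op, beam_spec(), 2e4, seed = 10, dr = 0.01,
                             dz = 0.01)
  a1 <- k1$totals$absorbed; a2 <- k2$totals$absorbed
  se <- sqrt(a1 * (1 - a1) / 2e4)
  expect_lt(abs(a1 - a2), 3 * sqrt(2) * se)
})

test_that("Monte Carlo error shrinks like one over root n", {
  op <- optical_properties(1.56, 12, 0)
  reps <- function(n) vapply(1:10, function(s)
    run_photon_transport(op, beam_spec(), n, seed = 100 + s,
                         dr = 0.05, dz = 0.05)$totals$absorbed, numeric(1))
  r1 <- stats::sd(reps(1500)); r2 <- stats::sd(reps(6000))
  expect_gt(r1 / r2, 1.2)     # expect ~2 with wide stochastic margin
  expect_lt(r1 / r2, 3.5)
})

test_that("ballistic and degenerate inputs raise errors", {
  expect_error(run_photon_transport(optical_properties(0, 0, 0), beam_spec()),
               "ballistic-transit")
  expect_error(run_photon_transport(optical_properties(), beam_spec(),
                                    n_photons = 0), "positive")
})

test_that("kernel revolution conserves power and preserves the axis profile", {
  k <- pe_cached("kernel_mua_only",
    run_photon_transport(optical_properties(1.56, 0, 0),
                         beam_spec(profile = "flat"), 1e5, seed = 3,
                         dr = 0.01, dz = 0.01))
  rv <- revolve_kernel(k, dx = 0.04, dz_out = 0.05, nsub = 5)
  expect_equal(rv$total, k$totals$absorbed_in_grid, tolerance = 5e-3)
  kbad <- k; kbad$dep[1] <- -1
  expect_error(revolve_kernel(kbad), "negative")
})

test_that("revolving an analytic flat-beam kernel preserves the axis profile", {
  # noise-free kernel: uniform irradiance inside r = 0.33, Beer-Lambert in z
  k <- pe_cached("kernel_mua_only", stop("built above"))
  ana <- k
  R <- 0.33; mua <- 1.56
  nrb <- round(R / k$dr)
  shell <- pi * ((seq_len(k$nr) * k$dr)^2 - ((seq_len(k$nr) - 1) * k$dr)^2)
  zfac <- exp(-mua * (seq_len(k$nz) - 1) * k$dz) - exp(-mua * seq_len(k$nz) * k$dz)
  ana$dep <- outer(ifelse(seq_len(k$nr) <= nrb, shell / (pi * R^2), 0), zfac)
  rv <- revolve_kernel(ana, dx = 0.04, dz_out = 0.05, nsub = 3)
  mid <- length(rv$xc) %/% 2
  kz <- 3
  # the on-axis 3D value equals the kernel's r ~ 0 density exactly (the
  # density is radially uniform inside the beam)
  expect_equal(rv$q[mid, mid, kz], kernel_density(ana, 1e-4, rv$zc[kz]),
               tolerance = 0.02)
  # and the axis z-profile follows the kernel's innermost column
  prof3d <- rv$q[mid, mid, ]
  profk <- kernel_density(ana, rep(1e-4, length(rv$zc)), rv$zc)
  expect_equal(prof3d, profk, tolerance = 0.02)
})

test_that("revolving a uniform ring kernel gives the analytic shell density", {
  # hand-built kernel: all power in the radial bin [0.2, 0.3] cm, depth
  # [0, 0.1] cm; the revolved density must equal P / (pi (r2^2 - r1^2) dz)
  k <- pe_cached("kernel_mua_only",
    run_photon_transport(optical_properties(1.56, 0, 0),
                         beam_spec(profile = "flat"), 1e5, seed = 3,
                         dr = 0.01, dz = 0.01))
  ring <- k
  ring$dep <- matrix(0, k$nr, k$nz)
  ring$dep[21:30, 1:10] <- 1 / (10 * 10)     # unit total in the ring block
  # analytic per-bin density of sub-ring [r1, r2]:
  dens_exact <- function(r) {
    ir <- floor(r / 0.01) + 1
    r1 <- (ir - 1) * 0.01; r2 <- ir * 0.01
    ifelse(r >= 0.2 & r < 0.3, (1 / 100) / (pi * (r2^2 - r1^2) * 0.01), 0)
  }
  expect_equal(kernel_density(ring, c(0.205, 0.251, 0.35), rep(0.05, 3)),
               dens_exact(c(0.205, 0.251, 0.35)))
  rv <- revolve_kernel(ring, dx = 0.02, dz_out = 0.02, nsub = 4)
  expect_equal(rv$total, 1, tolerance = 0.02)
})

test_that("the LED array superposes with a closed power ledger", {
  sp <- device_spec(0)
  gr <- pe_cached("grid_g1_shell",
    suppressWarnings(build_grid(sp, 2, nz_blood = 6)))
  k <- device_kernel()
  # single centred LED: all power lands in blood, none clipped
  one <- assemble_led_array(k, gr, layout = data.frame(x = 10, y = 10,
                                                       face = "top"))
  expect_equal(absorbed_power(one),
               0.92 * 0.036 * k$totals$absorbed, tolerance = 1e-6)
  expect_lt(one$totals$clipped, 1e-9)
  # full 40-LED array: absorbed + clipped = absorbed fraction x delivered
  full <- pe_cached("fluence_g1",
                    suppressWarnings(assemble_led_array(k, gr)))
  expect_equal(full$totals$absorbed_in_blood + full$totals$clipped,
               k$totals$absorbed * full$totals$delivered, tolerance = 1e-9)
  expect_equal(absorbed_power(full), full$totals$absorbed_in_blood,
               tolerance = 1e-6)
  expect_true(all(full$q >= 0))
  # symmetric footprint + symmetric layout: field symmetric under rotation
  qsum <- apply(full$q, c(1, 2), sum)
  expect_equal(qsum, qsum[rev(seq_len(nrow(qsum))), rev(seq_len(ncol(qsum)))],
               tolerance = 1e-9)
  # sources centred outside the footprint are excluded with a warning
  expect_warning(
    assemble_led_array(k, gr, layout = data.frame(x = -3, y = 10,
                                                  face = "top")),
    "outside the footprint")
})

test_that("optical property constructors validate and expose chromophores", {
  expect_equal(unname(chromophore_mu_a(c("HbCO", "HbO", "Hb"))),
               c(1.56, 1.12, 6.12))
  expect_error(chromophore_mu_a("XYZ"), "unknown")
  expect_error(optical_properties(-1), "mu_a")
  red <- blood_optics_620(reduced = TRUE)
  expect_equal(red$mu_s, 650 * (1 - 0.982))
  expect_identical(red$g, 0)
})
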